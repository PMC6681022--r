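# --- vocabulary -------------------------------------------------------------

dog_breeds <- c(
  "labrador", "labrador cross", "german shepherd", "jack russell terrier",
  "parson russell terrier", "shih tzu cross", "border collie", "kelpie",
  "staffordshire bull terrier", "cavalier king charles spaniel", "pug",
  "golden retriever", "siberian husky", "alaskan malamute", "maltese cross"
)
cat_breeds <- c(
  "domestic short hair", "domestic medium hair", "domestic long hair",
  "siamese", "burmese", "ragdoll", "british short hair", "russian blue"
)

plain_texts <- c(
  "Annual health check; all parameters within normal limits.",
  "Ear cleaning performed; mild wax accumulation.",
  "Nail trim and weight check.",
  "Dental check: mild tartar, advised home care.",
  "Repeat prescription dispensed, no examination.",
  "Mild gastroenteritis; supportive care and bland diet.",
  "Booster reminder letter printed for owner.",
  "Skin scrape negative; shampoo dispensed."
)

confounder_templates <- c(
  "Blood smear: %s hypochromic changes noted.",
  "Abdominal ultrasound performed with %s probe.",
  "Cytology report transcribed: occasional %s seen.",
  "Pathology comment mentions %s; clinical correlation advised."
)

# each template must trigger its own category's rule and no earlier rule
category_templates <- list(
  implantation_event = c(
    "Microchip implanted %CHIP%, batch sticker attached.",
    "Microchipped today under brief restraint; chip number %CHIP%.",
    "Microchip inserted between shoulder blades, no adverse reaction."
  ),
  blank_prepopulated_form = c(
    "Temp: __ Weight: __ Microchip: _____ Vacc due: __",
    "ADMISSION FORM - Microchip: ______ Diet: __ Insurance: __"
  ),
  preexisting_chip_confirmation = c(
    "Already microchipped; number confirmed on scan, %CHIP%.",
    "Boarding admission: microchip present and verified.",
    "Existing microchip checked against file; details correct."
  ),
  future_plan = c(
    "Plan to microchip at desexing next month.",
    "Microchip booked for next vaccination visit.",
    "Too small today; to be microchipped at next visit."
  ),
  admin_assistance = c(
    "Assisted client with change of ownership form for microchip registry.",
    "Updated microchip registry after owner's change of address."
  ),
  internal_number_request = c(
    "Note for nurse: collect microchip number for clinic records - still outstanding.",
    "Microchip number to be recorded in file; not yet done."
  ),
  stray_id_successful = c(
    "Stray dog brought in; scanned microchip and owner contacted, collected same day.",
    "Stray cat scanned, microchip registered, owner located and notified."
  ),
  stray_id_attempted = c(
    "Stray cat, microchip scanned but not registered; unable to identify owner.",
    "Stray presented after hours; microchip number has no owner details, held overnight."
  ),
  travel_requirements = c(
    "Preparing export paperwork; microchip number recorded on health certificate.",
    "Travel certificate completed; microchip verified for import permit."
  ),
  technical_problem = c(
    "Microchip failed to scan with two different readers; suspect faulty chip.",
    "Unreadable microchip; will retry scanning at revisit."
  ),
  contact_previous_owner = c(
    "Attempted to contact previous owner via microchip registry for history.",
    "Microchip traced to prior clinic; records requested."
  ),
  implantation_complication = c(
    "Small swelling at chip site two days after microchipping; monitor.",
    "Microchip has migrated to left elbow; owner informed of complication."
  ),
  other_word_or_typo = c(
    "Blood smear: microcytic hypochromic anaemia.",
    "Abdominal ultrasound with microconvex probe; no abnormalities.",
    "Cytology: occasional microclot noted."
  ),
  reported_lost = c(
    "Owner phoned: cat reported lost; microchip number passed to council ranger.",
    "Dog missing since Tuesday; microchip registry notified by owner."
  ),
  absence_noted = c(
    "Scanned on admission: no microchip found.",
    "New patient exam; not microchipped, advised owner of requirements."
  ),
  owner_refusal = c(
    "Owner declined microchipping at this time; no appointment made.",
    "Client refused microchip; discussed legislative requirement, owner adamant."
  ),
  none_of_the_above = c(
    "General discussion about microchips and registries; no action taken.",
    "Client asked how microchips work; brochure provided."
  )
)

# implantation texts using an alternative search-term variant ('m/c', 'mchip',
# 'micro c', 'micro-c'); real records use these abbreviations, and they give
# the secondary search terms of the ranking analysis something to find
alt_implant_templates <- c(
  "M/C implanted today; chip %CHIP%.",
  "Mchip implanted; sticker in file.",
  "Micro chip implanted under GA, no reaction.",
  "Micro-chip implanted prior to sale."
)

litter_templates <- c(
  "Litter of %N% pups all microchipped prior to sale.",
  "Dam's record: %N% kittens all microchipped and first vaccination given."
)

concurrent_texts <- c(
  vaccination_dog = "C5 vaccination given.",
  vaccination_cat = "F3 vaccination given.",
  spay = "Spay performed under GA.",
  castration = "Castration performed, routine recovery.",
  other_surgery = "Lump removal surgery performed.",
  other_consult = "Recheck of skin condition at same visit.",
  none = "No other procedures performed today."
)

# Table-3-style category mixtures: proportions over the 17 classes
valid_mixture_counts <- c(
  implantation_event = 257, blank_prepopulated_form = 458,
  preexisting_chip_confirmation = 203, future_plan = 25, admin_assistance = 9,
  internal_number_request = 8, stray_id_successful = 2, stray_id_attempted = 0,
  travel_requirements = 4, technical_problem = 1, contact_previous_owner = 2,
  implantation_complication = 6, other_word_or_typo = 2, reported_lost = 0,
  absence_noted = 5, owner_refusal = 0, none_of_the_above = 18
)
invalid_mixture_counts <- c(
  implantation_event = 155, blank_prepopulated_form = 385,
  preexisting_chip_confirmation = 164, future_plan = 73, admin_assistance = 7,
  internal_number_request = 9, stray_id_successful = 39, stray_id_attempted = 27,
  travel_requirements = 2, technical_problem = 1, contact_previous_owner = 1,
  implantation_complication = 0, other_word_or_typo = 7, reported_lost = 11,
  absence_noted = 87, owner_refusal = 19, none_of_the_above = 12
)

default_concurrent_mixture <- list(
  dog = c(vaccination = 179, spay = 14, castration = 15, other_surgery = 3,
          other_consult = 6, none = 9) / 226,
  cat = c(vaccination = 57, spay = 30, castration = 41, other_surgery = 2,
          other_consult = 2, none = 7) / 139
)

# duplicate-chip groups per patient at the cohort-level rate of roughly
# 1189 groups per 172,443 patients, split over the concordance classes
default_duplicate_counts <- c(
  full_match = 746, breed_mismatch = 335, sex_mismatch = 39,
  breed_and_sex_mismatch = 34, species_mismatch = 35
)

# --- configuration ----------------------------------------------------------

#' Solve a log-normal age model from its median and IQR
#'
#' For a log-normal distribution, `meanlog = log(median)` and the IQR is
#' `2 * median * sinh(z75 * sdlog)` with `z75` the 0.75 standard-normal
#' quantile, so `sdlog = asinh(IQR / (2 * median)) / z75` exactly.
#'
#' @param median_days Target median age (days).
#' @param iqr_days Target interquartile range (days).
#' @return Named numeric vector with `meanlog` and `sdlog`.
#' @export
#' @examples
#' solve_age_model(74.4, 95.23)
solve_age_model <- function(median_days, iqr_days) {
  if (median_days <= 0 || iqr_days < 0) abort("Targets must be positive.")
  c(
    meanlog = log(median_days),
    sdlog = asinh(iqr_days / (2 * median_days)) / qnorm(0.75)
  )
}

#' Configuration for the synthetic EPR generator
#'
#' Defaults encode the cohort structure the analysis assumes: 77.1% dogs,
#' 73.4% of records with a valid 15-digit chip field, hit-category mixtures
#' matching the valid (n = 1000) and invalid (n = 999) review samples,
#' species-specific concurrent-interaction mixtures, log-normal
#' age-at-implantation models with medians of 74.4 days (dogs) and 127.0
#' days (cats) and matching IQRs (95.23 / 131.45 days), cohort-specific
#' litter fractions (11/257 valid, 36/155 invalid) and date-of-birth
#' missingness (3/257, 18/155), and duplicated-chip injection scaled from
#' 1189 groups per 172,443 patients across the five concordance classes.
#'
#' @param n_patients Number of base patients to simulate.
#' @param dog_fraction Proportion of patients that are dogs.
#' @param valid_chip_fraction Proportion of patients with a valid chip field.
#' @param category_mixture,invalid_category_mixture Named probability
#'   vectors over [hit_categories()] for the two cohorts.
#' @param concurrent_mixture List with `dog` and `cat` probability vectors
#'   over [concurrent_classes()].
#' @param age_model List with `dog` and `cat` elements, each
#'   `list(median_days=, iqr_days=)`.
#' @param litter_fraction Named vector `c(valid=, invalid=)`: probability an
#'   implantation is a litter event, per cohort.
#' @param dob_missing Named vector `c(valid=, invalid=)`: probability the
#'   date of birth is absent, per cohort.
#' @param duplicate_injection Data frame with columns `class`,
#'   `multiplicity`, `count`: duplicated-chip groups to inject. A named
#'   integer vector is taken as pair counts per class. `NULL` scales the
#'   default class counts to `n_patients`.
#' @param confounder_rate Probability an ordinary consultation row contains
#'   a confounder word (a non-chip word containing "microc").
#' @param typo_rate Probability the word "microchip" in a hit row is
#'   misspelled ("microcip").
#' @param alt_term_rate Probability an individual implantation is written
#'   with an abbreviation ("m/c", "mchip", ...) instead of "microchip".
#' @param extra_rows Ordinary (non-hit) consultation rows per patient.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             dog_fraction = 0.771,
                             valid_chip_fraction = 0.734,
                             category_mixture = valid_mixture_counts / 1000,
                             invalid_category_mixture = invalid_mixture_counts / 999,
                             concurrent_mixture = default_concurrent_mixture,
                             age_model = list(
                               dog = list(median_days = 74.4, iqr_days = 95.23),
                               cat = list(median_days = 127.0, iqr_days = 131.45)
                             ),
                             litter_fraction = c(valid = 11 / 257, invalid = 36 / 155),
                             dob_missing = c(valid = 3 / 257, invalid = 18 / 155),
                             duplicate_injection = NULL,
                             confounder_rate = 0.002,
                             typo_rate = 0.02,
                             alt_term_rate = 0.03,
                             extra_rows = 2,
                             seed = 1) {
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  fractions <- c(dog_fraction, valid_chip_fraction, litter_fraction, dob_missing,
                 confounder_rate, typo_rate, alt_term_rate)
  if (any(fractions < 0 | fractions > 1)) abort("All fractions must lie in [0, 1].")
  for (mix in list(category_mixture, invalid_category_mixture,
                   concurrent_mixture$dog, concurrent_mixture$cat)) {
    if (abs(sum(mix) - 1) > 1e-9) abort("Mixture probabilities must sum to 1.")
    if (any(mix < 0)) abort("Mixture probabilities must be non-negative.")
  }
  if (!setequal(names(category_mixture), hit_categories()) ||
      !setequal(names(invalid_category_mixture), hit_categories())) {
    abort("Category mixtures must be named by the 17 hit categories.")
  }
  if (is.null(duplicate_injection)) {
    counts <- round(default_duplicate_counts * n_patients / 172443)
    duplicate_injection <- tibble::tibble(
      class = names(counts), multiplicity = 2L, count = as.integer(counts)
    )
  } else if (!is.data.frame(duplicate_injection)) {
    duplicate_injection <- tibble::tibble(
      class = names(duplicate_injection), multiplicity = 2L,
      count = as.integer(duplicate_injection)
    )
  }
  bad <- setdiff(duplicate_injection$class, concordance_classes)
  if (length(bad) > 0) abort(sprintf("Unknown concordance class: %s.", bad[1]))
  n_donors <- sum(duplicate_injection$count)
  if (n_donors > n_patients * valid_chip_fraction * 0.5) {
    abort("Infeasible config: too many duplicate groups for the corpus size.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      dog_fraction = dog_fraction,
      valid_chip_fraction = valid_chip_fraction,
      category_mixture = category_mixture[hit_categories()],
      invalid_category_mixture = invalid_category_mixture[hit_categories()],
      concurrent_mixture = concurrent_mixture,
      age_model = age_model,
      litter_fraction = litter_fraction,
      dob_missing = dob_missing,
      duplicate_injection = duplicate_injection,
      confounder_rate = confounder_rate,
      typo_rate = typo_rate,
      alt_term_rate = alt_term_rate,
      extra_rows = as.integer(extra_rows),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Sample ages at implantation
#'
#' Draws from the configured per-species log-normal model (see
#' [solve_age_model()]) and rounds to whole days with a floor of one day.
#'
#' @param n Number of draws.
#' @param species `"dog"` or `"cat"`.
#' @param age_model The `age_model` element of a [generator_config()].
#' @return Integer vector of ages in days. Uses the global RNG stream.
#' @export
sample_age <- function(n, species, age_model = generator_config(10)$age_model) {
  m <- age_model[[species]]
  p <- solve_age_model(m$median_days, m$iqr_days)
  pmax(1L, as.integer(round(rlnorm(n, p[["meanlog"]], p[["sdlog"]]))))
}

#' Render examination text for a hit category
#'
#' Draws one of the category's text templates; every template contains the
#' substring "microc" (Table-style hit categories classify search hits) and
#' triggers its own category's rule in [default_rules()].
#'
#' @param category A hit category.
#' @param chip Chip number substituted into templates that quote one.
#' @param litter Render a litter implantation text (implantation only)?
#' @return A single examination text string. Uses the global RNG stream.
#' @export
render_text <- function(category, chip = "956000000000001", litter = FALSE) {
  pool <- if (litter && category == "implantation_event") litter_templates
          else category_templates[[category]]
  if (is.null(pool)) abort(sprintf("Unknown category '%s'.", category))
  txt <- pool[sample.int(length(pool), 1)]
  txt <- sub("%CHIP%", chip, txt, fixed = TRUE)
  sub("%N%", sample(3:8, 1), txt, fixed = TRUE)
}

random_2017_dates <- function(n) {
  as.Date("2017-01-01") + sample.int(365, n, replace = TRUE) - 1
}

make_valid_chips <- function(n) {
  sprintf("956000%09d", sample.int(999999999L, n))
}

make_invalid_chips <- function(n) {
  kind <- sample(c("blank", "short", "alpha", "word"), n, replace = TRUE,
                 prob = c(0.55, 0.2, 0.15, 0.1))
  out <- character(n)
  out[kind == "blank"] <- ""
  k <- sum(kind == "short")
  out[kind == "short"] <- sprintf("95600%09d", sample.int(999999999L, k, replace = TRUE))
  k <- sum(kind == "alpha")
  out[kind == "alpha"] <- sprintf("95600%09dX", sample.int(999999999L, k, replace = TRUE))
  k <- sum(kind == "word")
  out[kind == "word"] <- sample(c("no chip", "pending", "TBA"), k, replace = TRUE)
  out
}

flip_sex <- function(x) ifelse(x == "male", "female", "male")

other_breed <- function(breed, species) {
  vapply(seq_along(breed), function(i) {
    pool <- if (species[i] == "dog") dog_breeds else cat_breeds
    pool <- setdiff(pool, breed[i])
    pool[sample.int(length(pool), 1)]
  }, character(1))
}

#' Generate a synthetic EPR corpus with ground truth
#'
#' Simulates a cohort of dog and cat patients, each with one "hit"
#' consultation row rendered from a hit-category template (so the row
#' contains the substring "microc") plus ordinary consultation rows, then
#' injects duplicated-chip patient groups of configured concordance
#' classes. Implantation rows carry species-appropriate ages
#' (visit date = date of birth + age) and concurrent-interaction text;
#' noise comes from misspellings of "microchip", abbreviation variants, and
#' confounder words in ordinary rows. Fully deterministic given the
#' config's seed.
#'
#' @param config A [generator_config()].
#' @return A list with `corpus` (a corpus tibble) and `truth`, itself a
#'   list: `records` (per-record true category, litter flag, concurrent
#'   events, age), `duplicates` (injected chip, class, multiplicity), and
#'   the `config`.
#' @export
#' @examples
#' sim <- generate_corpus(generator_config(n_patients = 200, seed = 42))
#' dplyr::count(dplyr::inner_join(sim$corpus, sim$truth$records, "record_id"),
#'              true_category)
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_patients

  # --- base patients ---------------------------------------------------
  species <- sample(c("dog", "cat"), n, replace = TRUE,
                    prob = c(config$dog_fraction, 1 - config$dog_fraction))
  sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                prob = c(0.49, 0.49, 0.02))
  breed <- ifelse(species == "dog",
                  sample(dog_breeds, n, replace = TRUE),
                  sample(cat_breeds, n, replace = TRUE))
  dob <- as.Date("2013-01-01") + sample.int(1600, n, replace = TRUE) - 1
  valid <- runif(n) < config$valid_chip_fraction
  chip <- character(n)
  chip[valid] <- make_valid_chips(sum(valid))
  chip[!valid] <- make_invalid_chips(sum(!valid))

  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    clinic_id = sprintf("C%03d", sample.int(40, n, replace = TRUE)),
    species = species, breed = breed, sex = sex,
    date_of_birth = dob, microchip = chip, chip_valid = valid
  )

  # --- duplicated-chip injection --------------------------------------
  inj <- config$duplicate_injection[config$duplicate_injection$count > 0, , drop = FALSE]
  dup_truth <- tibble::tibble(chip = character(0), class = character(0),
                              multiplicity = integer(0))
  clones <- patients[0, ]
  if (nrow(inj) > 0) {
    plan <- inj[rep(seq_len(nrow(inj)), inj$count), c("class", "multiplicity")]
    donors_idx <- sample(which(patients$chip_valid), nrow(plan))
    next_id <- n
    clone_list <- vector("list", nrow(plan))
    for (g in seq_len(nrow(plan))) {
      donor <- patients[donors_idx[g], ]
      cls <- plan$class[g]
      mult <- plan$multiplicity[g]
      mod <- donor
      if (cls == "species_mismatch") {
        mod$species <- ifelse(donor$species == "dog", "cat", "dog")
        mod$breed <- other_breed(donor$breed, mod$species)
      } else if (cls == "breed_and_sex_mismatch") {
        mod$breed <- other_breed(donor$breed, donor$species)
        mod$sex <- flip_sex(donor$sex)
      } else if (cls == "sex_mismatch") {
        mod$sex <- flip_sex(donor$sex)
      } else if (cls == "breed_mismatch") {
        mod$breed <- other_breed(donor$breed, donor$species)
      }
      members <- mod
      if (mult > 2) {
        # extra members identical to the donor: worst pairwise class unchanged
        members <- dplyr::bind_rows(mod, donor[rep(1, mult - 2), ])
      }
      members$patient_id <- sprintf("P%06d", next_id + seq_len(nrow(members)))
      members$clinic_id <- sprintf("C%03d", sample.int(40, nrow(members), replace = TRUE))
      next_id <- next_id + nrow(members)
      clone_list[[g]] <- members
    }
    clones <- dplyr::bind_rows(clone_list)
    dup_truth <- tibble::tibble(
      chip = patients$microchip[donors_idx],
      class = plan$class,
      multiplicity = as.integer(plan$multiplicity)
    )
  }
  patients <- dplyr::bind_rows(patients, clones)
  np <- nrow(patients)

  # --- one hit row per patient ----------------------------------------
  cohort <- ifelse(patients$chip_valid, "valid", "invalid")
  category <- character(np)
  for (co in c("valid", "invalid")) {
    mix <- if (co == "valid") config$category_mixture else config$invalid_category_mixture
    idx <- which(cohort == co)
    category[idx] <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
  }
  is_implant <- category == "implantation_event"
  litter <- is_implant & runif(np) < config$litter_fraction[cohort]
  dob_known <- runif(np) >= config$dob_missing[cohort]

  age <- rep(NA_integer_, np)
  for (sp in c("dog", "cat")) {
    idx <- which(is_implant & patients$species == sp)
    age[idx] <- sample_age(length(idx), sp, config$age_model)
  }
  visit <- random_2017_dates(np)
  has_age <- is_implant & dob_known
  visit[has_age] <- patients$date_of_birth[has_age] + age[has_age]
  late <- !has_age & dob_known & visit < patients$date_of_birth
  visit[late] <- patients$date_of_birth[late] +
    sample.int(700, sum(late), replace = TRUE)

  concurrent <- rep(NA_character_, np)
  indiv <- which(is_implant & !litter)
  for (sp in c("dog", "cat")) {
    mix <- config$concurrent_mixture[[sp]]
    idx <- indiv[patients$species[indiv] == sp]
    concurrent[idx] <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
  }
  text <- vapply(seq_len(np), function(i) {
    render_text(category[i], chip = patients$microchip[i], litter = litter[i])
  }, character(1))
  use_alt <- is_implant & !litter & runif(np) < config$alt_term_rate
  if (any(use_alt)) {
    text[use_alt] <- alt_implant_templates[
      sample.int(length(alt_implant_templates), sum(use_alt), replace = TRUE)]
    text[use_alt] <- vapply(which(use_alt), function(i) {
      sub("%CHIP%", patients$microchip[i], text[i], fixed = TRUE)
    }, character(1))
  }
  snippet <- dplyr::case_when(
    is.na(concurrent) ~ "",
    concurrent == "vaccination" & patients$species == "dog" ~
      concurrent_texts[["vaccination_dog"]],
    concurrent == "vaccination" ~ concurrent_texts[["vaccination_cat"]],
    TRUE ~ unname(concurrent_texts[concurrent])
  )
  text <- ifelse(snippet == "", text, paste(text, snippet))
  typo <- runif(np) < config$typo_rate
  text[typo] <- sub("microchip", "microcip", text[typo], ignore.case = TRUE)

  hit_rows <- tibble::tibble(
    patient_id = patients$patient_id,
    clinic_id = patients$clinic_id,
    species = patients$species,
    breed = patients$breed,
    sex = patients$sex,
    date_of_birth = dplyr::if_else(dob_known, patients$date_of_birth,
                                   as.Date(NA)),
    microchip = patients$microchip,
    visit_date = visit,
    examination_text = text,
    is_litter_record = litter,
    true_category = category,
    true_litter = litter,
    true_concurrent = concurrent,
    true_age_days = dplyr::if_else(has_age & !litter, age, NA_integer_)
  )

  # --- ordinary consultation rows -------------------------------------
  extra <- config$extra_rows
  if (extra > 0) {
    rep_idx <- rep(seq_len(np), each = extra)
    ne <- length(rep_idx)
    conf <- runif(ne) < config$confounder_rate
    etext <- sample(plain_texts, ne, replace = TRUE)
    if (any(conf)) {
      etext[conf] <- sprintf(
        sample(confounder_templates, sum(conf), replace = TRUE),
        sample(confounder_words, sum(conf), replace = TRUE)
      )
    }
    evisit <- random_2017_dates(ne)
    edob <- dplyr::if_else(dob_known[rep_idx], patients$date_of_birth[rep_idx],
                           as.Date(NA))
    late <- !is.na(edob) & evisit < edob
    evisit[late] <- edob[late] + sample.int(700, sum(late), replace = TRUE)
    extra_rows <- tibble::tibble(
      patient_id = patients$patient_id[rep_idx],
      clinic_id = patients$clinic_id[rep_idx],
      species = patients$species[rep_idx],
      breed = patients$breed[rep_idx],
      sex = patients$sex[rep_idx],
      date_of_birth = edob,
      microchip = patients$microchip[rep_idx],
      visit_date = evisit,
      examination_text = etext,
      is_litter_record = FALSE,
      true_category = dplyr::if_else(conf, "other_word_or_typo", NA_character_),
      true_litter = FALSE,
      true_concurrent = NA_character_,
      true_age_days = NA_integer_
    )
    all_rows <- dplyr::bind_rows(hit_rows, extra_rows)
  } else {
    all_rows <- hit_rows
  }

  all_rows <- all_rows[order(all_rows$patient_id, all_rows$visit_date), , drop = FALSE]
  all_rows$record_id <- seq_len(nrow(all_rows))
  corpus <- all_rows[, c("record_id", corpus_columns)]
  truth_records <- all_rows[, c("record_id", "patient_id", "true_category",
                                "true_litter", "true_concurrent", "true_age_days")]
  list(
    corpus = corpus,
    truth = list(records = truth_records, duplicates = dup_truth, config = config)
  )
}
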