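# build a one-row corpus record with sensible defaults
make_record <- function(record_id = 1L,
                        patient_id = "P000001",
                        clinic_id = "C001",
                        species = "dog",
                        breed = "labrador",
                        sex = "male",
                        date_of_birth = as.Date("2017-01-01"),
                        microchip = "956000012345678",
                        visit_date = as.Date("2017-03-16"),
                        examination_text = "Microchip implanted 956000012345678.",
                        is_litter_record = FALSE) {
  tibble::tibble(
    record_id = as.integer(record_id), patient_id = patient_id,
    clinic_id = clinic_id, species = species, breed = breed, sex = sex,
    date_of_birth = date_of_birth, microchip = microchip,
    visit_date = visit_date, examination_text = examination_text,
    is_litter_record = is_litter_record
  )
}

make_corpus <- function(...) {
  rows <- dplyr::bind_rows(...)
  rows$record_id <- seq_len(nrow(rows))
  rows
}

# truth categories aligned to the hits of `term` in a generated simulation
hit_truth <- function(sim, term = "microc") {
  h <- find_hits(sim$corpus, term)
  idx <- match(h$record_refs, sim$corpus$record_id)
  list(
    records = sim$corpus[idx, , drop = FALSE],
    category = sim$truth$records$true_category[
      match(h$record_refs, sim$truth$records$record_id)]
  )
}
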