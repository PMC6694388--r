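# Shared fixtures: hand-built bundles and maps small enough to reason about
# on paper, plus a compact simulated bundle reused across files.

# Claims bundle assembled row by row (no generator) for boundary tests.
hand_bundle <- function(adm, dx = NULL, months = NULL) {
  n <- nrow(adm)
  if (is.null(dx))
    dx <- data.frame(admission_id = character(), code = character(),
                     role = character(), poa = character(),
                     window = character(), stringsAsFactors = FALSE)
  enr <- data.frame(patient_id = adm$patient_id,
                    prior_ff_months = months %||% rep(24L, n),
                    stringsAsFactors = FALSE)
  validate_bundle(list(index_admissions = adm, diagnoses = dx,
                       enrollment = enr, truth = NULL))
}

adm_row <- function(id, age = 70, condition = "HF", hospital = "H1",
                    payment = 10000, died = 0L, patient = paste0("pt_", id)) {
  data.frame(admission_id = id, patient_id = patient, hospital_id = hospital,
             condition = condition, age_years = age, payment_30d = payment,
             died_30d = died, stringsAsFactors = FALSE)
}

dx_row <- function(id, code, role = "secondary", poa = "Y",
                   window = "index") {
  data.frame(admission_id = id, code = code, role = role,
             poa = if (window == "index") poa else NA_character_,
             window = window, stringsAsFactors = FALSE)
}

# Tiny handcrafted maps: cA->CC1 > cB,cD->CC2 > cC2->CC3; cX->CC4
# (excludable); cH->CC7; cE->CC2 and POA-exempt; cU unmapped.
tiny_maps <- function() {
  code_maps(
    code_to_cc = data.frame(
      code = c("cA", "cB", "cD", "cC2", "cX", "cH", "cE", "pHF"),
      cc = c("CC1", "CC2", "CC2", "CC3", "CC4", "CC7", "CC2", "CC20"),
      stringsAsFactors = FALSE),
    hierarchy = data.frame(group = "G1", rank = 1:3,
                           cc = c("CC1", "CC2", "CC3"),
                           stringsAsFactors = FALSE),
    poa_exempt = "cE",
    excludable_ccs = "CC4")
}

# One modest simulated bundle shared by property-style tests.
shared_bundle <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- generate_bundle(sim_config(n_patients = 4000, n_hospitals = 50,
                                         seed = 20))
    val
  }
})
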