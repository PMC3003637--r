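# shared fixtures and small generators for the test suite

all_study_tables <- function() {
  list(calibration = study_table("calibration"),
       dprpE = study_table("dprpE"),
       s168 = study_table("s168"))
}

pooled_strain_tables <- function() {
  rbind(study_table("dprpE"), study_table("s168"))
}

# random valid peptide sequence (uniform residue draw)
random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# a small known factor table for inverse-problem tests
known_k_table <- function() {
  retention_factor_table(c(I = 3.3, L = 4.0, M = 1.3, F = 6.4,
                           W = 9.7, Y = 3.6, V = 1.1))
}
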