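# small deterministic fixtures built in code

make_records <- function(n_per_diet = 2, diets = default_diets()) {
  rows <- do.call(rbind, lapply(seq_len(nrow(diets)), function(i) {
    data.frame(animal_id = sprintf("a%02d", seq_len(n_per_diet)),
               diet_id = diets$diet_id[i],
               period = i,
               bw_kg = 200 + 5 * seq_len(n_per_diet),
               dmi_obs = 4.5 + 0.1 * i + 0.05 * seq_len(n_per_diet),
               dmi_sim = 4.8 + 0.1 * i,
               ch4_obs = 150 + 2 * i + seq_len(n_per_diet),
               ch4_sim = 100 + 2 * i,
               stringsAsFactors = FALSE)
  }))
  animal_records(rows)
}

table1_ranges <- function(diets = default_diets()) {
  vars <- c("ndf", "nsc", "ee", "ash", "cp", "ivdmd")
  stats::setNames(lapply(vars, function(v) range(diets[[v]])), vars)
}

expected_signs <- c(ndf = -1L, nsc = -1L, ee = -1L, ash = -1L,
                    cp = 1L, ivdmd = 1L)
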