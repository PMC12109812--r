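# Shared fixtures built in code.

# A count table with exact per-animal GFP fractions at a single stage.
records_with_fractions <- function(fracs, n = 100, stage = "adult",
                                   region = "cgc", cohort = "c") {
  pos <- round(fracs * n)
  data.frame(
    cohort = cohort,
    animal_id = sprintf("a%02d", seq_along(fracs)),
    region = region,
    stage = stage,
    n_gfp_pos = pos,
    n_gfp_neg = n - pos,
    stringsAsFactors = FALSE
  )
}

# Mosaic records with exact stage fractions shared by all animals.
records_with_stage_fractions <- function(stage_fracs, n_animals = 3, n = 1000,
                                         cohort = "mosaic") {
  do.call(rbind, lapply(seq_len(n_animals), function(i) {
    data.frame(
      cohort = cohort,
      animal_id = sprintf("a%02d", i),
      region = "cgc",
      stage = names(stage_fracs),
      n_gfp_pos = round(stage_fracs * n),
      n_gfp_neg = n - round(stage_fracs * n),
      stringsAsFactors = FALSE
    )
  }))
}

wt_config <- function(seed, n_animals = 8, n_cells = 500, s = 1, ...) {
  sim_config(n_animals = n_animals, n_cells_per_region = n_cells,
             stages = "adult", survival = survival_spec(s), seed = seed, ...)
}
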