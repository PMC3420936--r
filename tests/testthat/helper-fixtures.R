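# shared fixtures, built once per test run
survey_curve <- function() {
  if (is.null(.fixture_env$curve))
    .fixture_env$curve <- fit_calibration(calibration_pairs_from_survey())
  .fixture_env$curve
}
.fixture_env <- new.env()

# counts sheet regenerated from printed WT efficiencies (1000 colonies/plate,
# three identical replicates) for pipeline round-trips
wt_counts_sheet <- function() {
  t1 <- paper_fixture_tables()$table1
  wt <- t1[t1$genotype == "WT" & !t1$position %in% c(57.64, 57.65), ]
  do.call(rbind, lapply(seq_len(nrow(wt)), function(i) {
    data.frame(strain_id = wt$strain[i], position_cs = wt$position[i],
               genotype = "WT", condition = "none", replicate_id = 1:3,
               white_count = round(1000 * wt$efficiency[i]), total_count = 1000)
  }))
}
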