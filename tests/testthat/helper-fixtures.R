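# shared expensive fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

# a Table-2-calibrated feature table at study scale, with its scaled /
# filtered derivatives and the default UMAP embedding
calibrated_fixture <- function() {
  if (is.null(.fixture_env$calibrated)) {
    des <- cohort_design(cells_per_roi = 24, seed = 11)  # 3072 cells
    tab <- generate_feature_table(des)
    scaled <- zscore_scale(drop_incomplete_cells(tab))
    corr <- correlation_matrix(scaled)
    retained <- suppressMessages(filter_redundant_features(corr, 0.9))
    emb <- umap_embed(scaled, seed = 42, features = retained)
    .fixture_env$calibrated <- list(design = des, table = tab,
                                    scaled = scaled, corr = corr,
                                    retained = retained, embedding = emb)
  }
  .fixture_env$calibrated
}

# truth-labelled per-cell state assignments (bypassing clustering) for the
# statistics module
truth_assignments <- function(cells_per_roi = 20, seed = 3) {
  des <- cohort_design(cells_per_roi = cells_per_roi, seed = seed)
  tab <- generate_feature_table(des)
  tab$state <- c(ramified = "surveillant", rod = "primed",
                 amoeboid = "activated")[tab$class]
  tab
}
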