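# Small cohort configurations used across tests (fast to generate).

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 40L, n_planted_genes = 4L, n_taxa = 50L,
               n_planted_taxa = 3L, planted_family_size = 2L,
               tissues = c("eWAT", "liver"), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# Noiseless configuration: every stochastic layer switched off so generator
# post-conditions hold exactly.
noiseless_config <- function(seed = 1, ...) {
  args <- list(seed = seed, noise_sd_bw = 0, noise_cv_expr = 0,
               baseline_bw_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(small_config, args)
}

# Hand-built growth/metadata pair: two mice per colonization group following
# exact lines bw = b0 + s * week over weeks 0..8.
toy_growth <- function(slope_gf = 0.3, slope_fmt = 0.6, diet = "ND",
                       weeks = 0:8, b0 = c(20, 21)) {
  rows <- list()
  md <- list()
  for (col in c("GF", "FMT")) {
    s <- if (col == "FMT") slope_fmt else slope_gf
    for (i in seq_along(b0)) {
      id <- sprintf("%s_%s_m%d", diet, col, i)
      rows[[length(rows) + 1]] <- data.frame(mouse_id = id, week = weeks,
                                             bw_g = b0[i] + s * weeks)
      md[[length(md) + 1]] <- data.frame(sample_id = paste0(id, ".feces"),
                                         mouse_id = id, colonization = col,
                                         diet = diet, tissue = "feces",
                                         week = max(weeks))
    }
  }
  list(growth = do.call(rbind, rows), metadata = do.call(rbind, md))
}
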