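# Shared fixtures: all synthetic, built in code at test time.

# A tiny raw cohort written to disk in load_cohort's file dialect.
write_tiny_cohort <- function(dir, n_subjects = 3L, t_len = 240L, r = 116L,
                              seed = 1L) {
  set.seed(seed)
  atlas <- synthetic_atlas(r)
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  for (sid in ids) {
    m <- matrix(rnorm(t_len * r), t_len, r)
    write.table(m, file.path(dir, "series", paste0(sid, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(
    subject_id = ids,
    group = rep(c("control", "patient"), length.out = n_subjects),
    age = 25 + seq_len(n_subjects), sex = "female",
    education = 12, site = "site1", mean_fd = 0.1, hamd = NA)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  invisible(list(manifest = file.path(dir, "manifest.csv"),
                 series = file.path(dir, "series"),
                 atlas = file.path(dir, "atlas.csv")))
}

# Frames drawn exactly from k mutually uncorrelated row patterns.
orthogonal_frame_pool <- function(k = 3L, r = 24L, frames_per = 10L) {
  templates <- matrix(0, k, r)
  block <- r %/% k
  for (i in seq_len(k)) {
    templates[i, ((i - 1) * block + 1):(i * block)] <- 1
    templates[i, ] <- templates[i, ] - mean(templates[i, ])
  }
  pool <- templates[rep(seq_len(k), each = frames_per), ]
  list(pool = pool, templates = templates,
       truth = rep(seq_len(k), each = frames_per))
}

# A random irreducible row-stochastic matrix (all entries positive).
random_chain <- function(k, concentration = 1) {
  p <- matrix(rgamma(k * k, concentration) + 1e-3, k, k)
  p / rowSums(p)
}

# A small fake standardized roi_ts built directly from a matrix.
fake_series <- function(data, id = "s", tr = 2, standardized = TRUE) {
  ts <- roi_ts(data, id, tr_seconds = tr)
  ts$standardized <- standardized
  ts
}
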