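# Small fixtures built in code.

# A labelled triangle and transformed copies.
tri_a <- matrix(c(0, 0, 1, 0, 0.3, 0.8), ncol = 2, byrow = TRUE)
tri_b <- matrix(c(0, 0, 1, 0.1, 0.5, 0.9), ncol = 2, byrow = TRUE)

similarity_transform <- function(x, theta = 0.7, scale = 2.3, shift = c(5, -3)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(scale * x %*% R, 2, shift, `+`)
}

# Ten-measurement toy jaw with hand-computable character ratios.
toy_jaw <- data.frame(
  taxon_id = "toy",
  jaw_length = 12, tooth_row_length = 6, max_depth = 3,
  symphysis_length = 2.4, symphysis_angle = 30,
  inlever_closing = 2, inlever_opening = 1.5,
  outlever_anterior = 10, outlever_posterior = 5,
  articulation_offset_raw = 0.6)

# Gaussian blob matrix with planted labels.
make_blobs <- function(n_per, centers, sd = 1, seed = 1, dim = ncol(centers)) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
    matrix(rnorm(n_per * dim, 0, sd), n_per, dim) +
      matrix(centers[g, ], n_per, dim, byrow = TRUE)))
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Write a small TPS file and return its path.
write_tps_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tps", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_taxa <- data.frame(
  taxon_id = c("t1", "t2", "t3", "t4"),
  clade = c("A", "A", "B", "B"),
  subclade = c("A1", "A2", "B1", "B1"),
  first_bin = c("Induan", "Olenekian", "Induan", "Anisian"),
  last_bin = c("Anisian", "Olenekian", "Olenekian", "Anisian"),
  diet = "herbivore", stringsAsFactors = FALSE)
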