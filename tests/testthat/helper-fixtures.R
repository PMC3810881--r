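# Small in-code fixtures shared across test files.

# Hand-sized occurrence matrix: 4 taxa x 3 ecoregions.
toy_occ <- function() {
  inc <- matrix(c(1, 1, 0,
                  0, 1, 1,
                  1, 0, 0,
                  1, 1, 1), nrow = 4L, byrow = TRUE,
                dimnames = list(c("t1", "t2", "t3", "t4"),
                                c("A", "B", "C")))
  occurrence_matrix(inc, c("endemic", "nonendemic", "endemic",
                           "nonendemic"),
                    c("baetic_only", NA, "both", NA))
}

# Random incidence matrix with guaranteed non-empty rows and columns.
random_occ <- function(n_taxa, n_eco, p = 0.4) {
  repeat {
    inc <- matrix(stats::runif(n_taxa * n_eco) < p, n_taxa, n_eco,
                  dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                  sprintf("e%02d", seq_len(n_eco))))
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0)) break
  }
  occurrence_matrix(inc, rep("nonendemic", n_taxa))
}

# Flora matching the printed pool counts: 4450 taxa over one hotspot
# and one outside ecoregion; 667 endemics (485/129/53 range classes)
# and 3384 nonendemics in the hotspot, 399 taxa outside only.
printed_count_pool <- function() {
  n_end <- 667L; n_non <- 3384L; n_out <- 399L
  n <- n_end + n_non + n_out
  inc <- matrix(FALSE, n, 2L,
                dimnames = list(sprintf("sp%04d", seq_len(n)),
                                c("HOT", "OUT")))
  inc[seq_len(n_end + n_non), "HOT"] <- TRUE
  inc[n_end + n_non + seq_len(n_out), "OUT"] <- TRUE
  flags <- c(rep("endemic", n_end), rep("nonendemic", n_non + n_out))
  rc <- c(rep("baetic_only", 485L), rep("rifan_only", 129L),
          rep("both", 53L), rep(NA_character_, n_non + n_out))
  info <- data.frame(id = c("HOT", "OUT"),
                     name = c("hotspot", "lowland"),
                     region = c("core", "edge"),
                     in_hotspot = c(TRUE, FALSE),
                     in_baetic = c(TRUE, FALSE),
                     area_km2 = c(1000, 500))
  list(occ = occurrence_matrix(inc, flags, rc), info = info)
}

# Monthly cell table with constant values per cell, handy for
# closed-form checks of the 22-variable construction.
monthly_cells_fixture <- function(eco, elev, tmean, prec,
                                  tmax = tmean + 5, tmin = tmean - 5) {
  n <- length(eco)
  stopifnot(length(elev) == n)
  as_mat <- function(v) {
    if (is.matrix(v)) v else matrix(rep(v, each = n), n, 12L)
  }
  df <- data.frame(ecoregion = eco, elev_m = elev)
  blocks <- list(tmean = as_mat(tmean), tmax = as_mat(tmax),
                 tmin = as_mat(tmin), prec = as_mat(prec))
  for (p in names(blocks)) {
    m <- blocks[[p]]
    colnames(m) <- sprintf("%s_%02d", p, 1:12)
    df <- cbind(df, m)
  }
  df
}

# Environmental table built directly from raw variable columns.
env_fixture <- function(ids, ...) {
  data.frame(ecoregion = ids, ..., check.names = FALSE,
             row.names = ids)
}

# Symmetric random distance matrix from points in the plane.
random_geo_dm <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xy <- matrix(stats::runif(2L * n, 0, 10), n, 2L)
  labs <- sprintf("e%02d", seq_len(n))
  distance_matrix(as.matrix(stats::dist(xy)), labs)
}
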