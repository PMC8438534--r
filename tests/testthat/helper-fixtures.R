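# Shared fixtures: all built in code at test time.

# random scattered point set (pixel centers) on a grid; hull stays small
random_point_mask <- function(seed, n_min = 60, n_max = 300, extent = 200) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  unique(cbind(sample.int(extent, n, replace = TRUE) - 1L,
               sample.int(extent, n, replace = TRUE) - 1L))
}

# filled disk mask of given pixel radius
disk_mask <- function(radius = 50L, pad = 5L) {
  size <- 2L * (radius + pad) + 1L
  ctr <- radius + pad # 0-based center
  g <- expand.grid(r = 0:(size - 1L), c = 0:(size - 1L))
  inside <- (g$r - ctr) ^ 2 + (g$c - ctr) ^ 2 <= radius ^ 2
  m <- matrix(FALSE, size, size)
  m[cbind(g$r + 1L, g$c + 1L)] <- inside
  m
}

mask_from_points <- function(pts, nrow_ = NULL, ncol_ = NULL) {
  nrow_ <- nrow_ %||% (max(pts[, 1L]) + 2L)
  ncol_ <- ncol_ %||% (max(pts[, 2L]) + 2L)
  m <- matrix(FALSE, nrow_, ncol_)
  m[pts + 1L] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook balanced two-way sums of squares by explicit summation;
# independent of stats::aov
hand_anova_ss <- function(table, trait) {
  y <- table[[trait]]
  g <- table$genotype
  t <- table$treatment
  gm <- mean(y)
  cell <- tapply(y, list(g, t), mean)
  gmean <- tapply(y, g, mean)
  tmean <- tapply(y, t, mean)
  r <- length(y) / (length(gmean) * length(tmean))
  ss_g <- r * length(tmean) * sum((gmean - gm) ^ 2)
  ss_t <- r * length(gmean) * sum((tmean - gm) ^ 2)
  ss_cells <- r * sum((cell - gm) ^ 2)
  ss_gt <- ss_cells - ss_g - ss_t
  ss_tot <- sum((y - gm) ^ 2)
  c(genotype = ss_g, concentration = ss_t, interaction = ss_gt,
    error = ss_tot - ss_cells, total = ss_tot)
}

# small balanced demo table with hand-settable values
demo_table <- function(values, genotypes = c("A", "B"), reps = 2L) {
  grid <- expand.grid(rep = seq_len(reps),
                      treatment = c("control", "deficient"),
                      genotype = genotypes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("genotype", "treatment", "rep")]
  grid$y <- values
  tibble::as_tibble(grid)
}
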