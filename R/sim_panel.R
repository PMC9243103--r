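#' Simulate an LD reference panel
#'
#' Generates a diploid dosage panel with block-wise linkage disequilibrium.
#' Within each block the two latent haplotype Gaussians follow an AR(1)
#' process with parameter \code{block_rho}, so the latent correlation between
#' variants i and j in the same block is \code{block_rho^|i-j|}; thresholding
#' each latent value at the variant's MAF quantile yields alleles, and the
#' dosage is their sum. Blocks are mutually independent. The panel stands in
#' for an external haplotype reference (e.g. a 1000-genomes-style European
#' panel) wherever LD is needed downstream.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_individuals Number of diploid individuals in the panel.
#' @param rng Optional \code{seed} override; by default \code{config$seed}
#'   is used, offset so the panel draw is independent of other generator
#'   calls under the same config.
#'
#' @return An object of class \code{reference_panel}: a list with
#'   \code{variants} (data.frame: id, chrom, pos, a1 effect allele, a2,
#'   maf, block), \code{genotypes} (n_individuals x n_variants integer
#'   matrix of dosages in {0,1,2}), and \code{block_rho}.
#' @export
simulate_reference_panel <- function(config, n_individuals = 1000L,
                                     rng = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_individuals <- check_count(n_individuals, "n_individuals")
  seed <- if (is.null(rng)) config$seed else check_count(rng, "rng", 0L)

  m <- config$n_variants
  block_size <- m %/% config$n_blocks
  rho <- config$block_rho

  # all randomness through one local RNG stream; no global state leaks
  gen <- local_rng(seed, stream = 1L)
  maf <- gen$runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(1 - maf)  # latent > thr  =>  carries effect allele

  dose <- matrix(0L, n_individuals, m)
  for (hap in 1:2) {
    lat <- matrix(NA_real_, n_individuals, m)
    for (b in seq_len(config$n_blocks)) {
      cols <- ((b - 1L) * block_size + 1L):(b * block_size)
      z <- gen$rnorm(n_individuals)
      lat[, cols[1]] <- z
      if (block_size > 1L) {
        sd_innov <- sqrt(1 - rho^2)
        for (j in 2:block_size) {
          z <- rho * z + sd_innov * gen$rnorm(n_individuals)
          lat[, cols[j]] <- z
        }
      }
    }
    dose <- dose + (lat > rep(thr, each = n_individuals))
  }
  storage.mode(dose) <- "integer"

  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = 1L,
    pos = 1L + (seq_len(m) - 1L) * config$pos_spacing_bp,
    a1 = "A", a2 = "G",
    maf = maf,
    block = rep(seq_len(config$n_blocks), each = block_size),
    stringsAsFactors = FALSE)
  colnames(dose) <- variants$id

  structure(list(variants = variants, genotypes = dose,
                 block_rho = rho),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d individuals x %d variants, %d blocks (rho = %.2f)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$variants$block)), x$block_rho))
  invisible(x)
}

# A self-contained RNG stream: evaluates draws under a saved seed without
# touching the caller's .Random.seed.
local_rng <- function(seed, stream = 0L) {
  state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed + 1000003L * stream)
    else assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rbinom = function(n, size, prob) draw(stats::rbinom, n, size, prob),
    sample = function(x, size, replace = FALSE, prob = NULL)
      draw(base::sample, x, size, replace, prob)
  )
}

#' Pairwise dosage correlation (r-squared) from a panel
#'
#' Squared Pearson correlation between dosage columns, the LD measure used
#' for clumping, locus definition and LD scores.
#'
#' @param panel A \code{reference_panel}.
#' @param ids Optional character vector of variant ids (default: all).
#' @return A symmetric matrix of r-squared values with unit diagonal.
#' @export
panel_r2 <- function(panel, ids = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  g <- panel$genotypes
  if (!is.null(ids)) {
    miss <- setdiff(ids, colnames(g))
    if (length(miss))
      stop_param("variants absent from panel: %s",
                 paste(utils::head(miss, 5), collapse = ", "))
    g <- g[, ids, drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(g))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r^2
}
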