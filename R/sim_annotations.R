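#' Simulate gene models, gene sets and a drug-target/ATC table
#'
#' Tiles non-overlapping gene intervals along the panel (one gene per run of
#' consecutive variants), samples gene sets without replacement, and builds
#' a drug-target table in which a configurable fraction of sets is
#' "druggable": every druggable set contains at least one gene that is the
#' target of a drug carrying an ATC code.
#'
#' @param panel A \code{reference_panel}.
#' @param n_genes Number of genes; each gene spans
#'   \code{floor(n_variants / n_genes)} consecutive variants.
#' @param n_sets Number of gene sets.
#' @param set_size_range Genes per set, drawn uniformly from this range
#'   (minimum 5, matching the downstream at-least-five-overlapping-genes
#'   filter).
#' @param druggable_fraction Fraction of sets flagged druggable (each gets
#'   >= 1 drug-target gene with an ATC code).
#' @param n_atc_codes Number of distinct ATC level codes to spread targets
#'   across.
#' @param seed Integer seed.
#' @return List of class \code{sim_annotations}: \code{genes} (data.frame
#'   GENE, CHR, START, END, STRAND; 1-based inclusive), \code{sets} (named
#'   list of gene-id vectors), \code{druggable} (logical per set), and
#'   \code{atc} (data.frame DRUG, ATC_CODE, GENE).
#' @export
simulate_annotations <- function(panel, n_genes = 50L, n_sets = 20L,
                                 set_size_range = c(5L, 15L),
                                 druggable_fraction = 0.5,
                                 n_atc_codes = 8L, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  v <- panel$variants
  m <- nrow(v)
  n_genes <- check_count(n_genes, "n_genes")
  span <- m %/% n_genes
  if (span < 1L)
    stop_param("n_genes (%d) exceeds available variant intervals (%d)",
               n_genes, m)
  if (set_size_range[1] < 5L)
    stop_param("minimum set size is 5 genes")
  if (set_size_range[2] > n_genes)
    stop_param("set sizes cannot exceed n_genes")
  check_prob(druggable_fraction, "druggable_fraction", open_lower = FALSE,
             open_upper = FALSE)

  gen <- local_rng(check_count(seed, "seed", 0L), stream = 8L)
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  start_idx <- (seq_len(n_genes) - 1L) * span + 1L
  end_idx <- start_idx + span - 1L
  strand <- c("+", "-")[1L + (gen$runif(n_genes) > 0.5)]
  genes <- data.frame(GENE = gene_ids, CHR = 1L,
                      START = v$pos[start_idx],
                      END = v$pos[end_idx],
                      STRAND = strand, stringsAsFactors = FALSE)

  sizes <- set_size_range[1] +
    floor(gen$runif(n_sets) * (set_size_range[2] - set_size_range[1] + 1L))
  sizes <- pmin(sizes, n_genes)
  sets <- lapply(seq_len(n_sets), function(i)
    sort(gene_ids[gen$sample(n_genes, sizes[i])]))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))

  n_drug <- round(druggable_fraction * n_sets)
  druggable <- rep(FALSE, n_sets)
  if (n_drug > 0L) druggable[gen$sample(n_sets, n_drug)] <- TRUE
  names(druggable) <- names(sets)

  atc_codes <- sprintf("X%02d", seq_len(n_atc_codes))
  atc_rows <- list()
  di <- 0L
  for (si in which(druggable)) {
    di <- di + 1L
    target <- sets[[si]][1L + floor(gen$runif(1) * length(sets[[si]]))]
    code <- atc_codes[1L + ((di - 1L) %% n_atc_codes)]
    atc_rows[[di]] <- data.frame(DRUG = sprintf("DRUG%03d", di),
                                 ATC_CODE = code, GENE = target,
                                 stringsAsFactors = FALSE)
  }
  atc <- if (length(atc_rows)) do.call(rbind, atc_rows) else
    data.frame(DRUG = character(), ATC_CODE = character(),
               GENE = character(), stringsAsFactors = FALSE)

  structure(list(genes = genes, sets = sets, druggable = druggable,
                 atc = atc),
            class = "sim_annotations")
}
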