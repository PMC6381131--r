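#' Build a DEG table
#'
#' @param gene_id character vector of unique gene ids.
#' @param log_fc signed log fold changes, finite.
#' @param significant logical significance flags (precomputed upstream;
#'   differential-expression testing itself is out of scope).
#' @return data.frame of class `"deg_table"`.
#' @export
deg_table <- function(gene_id, log_fc, significant) {
  n <- length(gene_id)
  if (length(log_fc) != n || length(significant) != n)
    stop("columns must have equal length", call. = FALSE)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids", call. = FALSE)
  stop_if_not_finite(log_fc, "log_fc")
  structure(
    data.frame(gene_id = as.character(gene_id), log_fc = log_fc,
               significant = as.logical(significant),
               stringsAsFactors = FALSE),
    class = c("deg_table", "data.frame")
  )
}

#' DEG set intersection and sign concordance
#'
#' The set/sign logic behind "commonly regulated" gene lists: `common` is
#' the intersection of the two significant-gene sets; `concordant` are the
#' common genes whose fold-change signs agree (both strictly up or both
#' strictly down); `discordant` is the rest. A zero log fold change counts
#' as neither up nor down, so a common gene with `log_fc == 0` in either
#' table is discordant (listed separately in `zero_lfc`).
#'
#' @param a,b [deg_table()] objects sharing a gene namespace.
#' @return list with gene-id character vectors `common`, `concordant`,
#'   `discordant`, `zero_lfc`, and counts `n_common`, `n_concordant`,
#'   `n_discordant`.
#' @examples
#' a <- deg_table(c("g1", "g2"), c(1, -2), c(TRUE, TRUE))
#' b <- deg_table(c("g1", "g2"), c(2, 0.5), c(TRUE, TRUE))
#' deg_overlap(a, b)$n_concordant  # 1
#' @export
deg_overlap <- function(a, b) {
  a <- as_deg_table(a, "a"); b <- as_deg_table(b, "b")
  common <- sort(intersect(a$gene_id[a$significant], b$gene_id[b$significant]))
  lfa <- a$log_fc[match(common, a$gene_id)]
  lfb <- b$log_fc[match(common, b$gene_id)]
  conc <- sign(lfa) == sign(lfb) & lfa != 0 & lfb != 0
  list(common = common,
       concordant = common[conc],
       discordant = common[!conc],
       zero_lfc = common[lfa == 0 | lfb == 0],
       n_common = length(common),
       n_concordant = sum(conc),
       n_discordant = sum(!conc))
}

as_deg_table <- function(x, name) {
  if (inherits(x, "deg_table")) return(x)
  need <- c("gene_id", "log_fc", "significant")
  if (is.data.frame(x) && all(need %in% names(x)))
    return(deg_table(x$gene_id, x$log_fc, x$significant))
  stop(sprintf("'%s' must be a deg_table or a data.frame with columns %s",
               name, paste(need, collapse = ", ")), call. = FALSE)
}

#' Simulate a pair of DEG tables with controlled overlap
#'
#' Generates two tables over a shared gene namespace whose significant sets
#' intersect in exactly `n_common` genes, of which exactly `n_concordant`
#' share the fold-change sign — ground truth for [deg_overlap()].
#'
#' @param n_genes genes per table (shared namespace).
#' @param n_common size of the significant-set intersection.
#' @param n_concordant number of common genes with agreeing signs; must
#'   satisfy `n_concordant <= n_common <= n_genes`.
#' @param seed RNG seed.
#' @param frac_significant fraction of genes flagged significant in each
#'   table (default 0.4; clamped so the construction stays feasible).
#' @return list with `a`, `b` ([deg_table()]s) and `ground_truth` (the
#'   common and concordant gene-id sets).
#' @export
simulate_deg_tables <- function(n_genes, n_common, n_concordant, seed = 0,
                                frac_significant = 0.4) {
  if (!(n_concordant <= n_common && n_common <= n_genes) ||
      n_concordant < 0 || n_genes < 1)
    stop("need 0 <= n_concordant <= n_common <= n_genes", call. = FALSE)
  withr::with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    n_sig <- max(n_common, min(n_genes, round(frac_significant * n_genes)))
    # disjoint extras are possible only if the namespace is big enough
    extra <- min(n_sig - n_common, (n_genes - n_common) %/% 2)
    n_sig <- n_common + extra
    perm <- sample(genes)
    common <- perm[seq_len(n_common)]
    rest <- perm[-seq_len(n_common)]
    sig_a <- c(common, utils::head(rest, extra))
    sig_b <- c(common, utils::head(rest[-seq_len(max(extra, 0))], extra))
    lfc_a <- stats::rnorm(n_genes, 0, 2)
    lfc_a[lfc_a == 0] <- 0.1
    lfc_b <- stats::rnorm(n_genes, 0, 2)
    lfc_b[lfc_b == 0] <- 0.1
    names(lfc_a) <- names(lfc_b) <- genes
    if (n_common > 0) {
      conc <- common[seq_len(n_concordant)]
      disc <- setdiff(common, conc)
      lfc_b[conc] <- abs(lfc_b[conc]) * sign(lfc_a[conc])
      lfc_b[disc] <- -abs(lfc_b[disc]) * sign(lfc_a[disc])
    }
    a <- deg_table(genes, lfc_a, genes %in% sig_a)
    b <- deg_table(genes, lfc_b, genes %in% sig_b)
    list(a = a, b = b,
         ground_truth = list(common = sort(common),
                             concordant = sort(common[seq_len(n_concordant)]),
                             n_common = n_common,
                             n_concordant = n_concordant))
  })
}
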