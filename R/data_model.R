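#' Allele-resolved read counts for one gene
#'
#' The unit of inference: for gene \eqn{g} with \eqn{J_g} SNPs and \eqn{K}
#' biological replicates, `y[j, k]` holds the maternal-allele read count
#' \eqn{y_{gjk}} and `n[j, k]` the total count \eqn{n_{gjk}} of cell
#' \eqn{(j, k)}.  Cells can be missing (not every replicate is heterozygous at
#' every SNP); unobserved cells carry no counts and are excluded from all
#' likelihoods.
#'
#' @param gene_id single gene identifier.
#' @param y,n \eqn{J_g \times K} integer matrices of maternal and total
#'   counts; `NA` in unobserved cells.
#' @param snp_ids,rep_ids unique SNP / replicate labels; default taken from
#'   `dimnames(n)` or generated.  SNP order is kept as given (genomic order
#'   by convention).
#' @param observed logical \eqn{J_g \times K} mask; default: cells where `n`
#'   is not `NA`.
#' @return an object of class `"ase_counts"`.
#' @export
ase_counts <- function(gene_id, y, n, snp_ids = NULL, rep_ids = NULL,
                       observed = NULL) {
  y <- as.matrix(y)
  n <- as.matrix(n)
  stopifnot(identical(dim(y), dim(n)), nrow(y) >= 1L, ncol(y) >= 1L)
  if (is.null(observed)) observed <- !is.na(n)
  observed <- as.matrix(observed)
  stopifnot(identical(dim(observed), dim(n)))
  if (is.null(snp_ids)) snp_ids <- rownames(n)
  if (is.null(snp_ids)) snp_ids <- paste0("s", seq_len(nrow(n)))
  if (is.null(rep_ids)) rep_ids <- colnames(n)
  if (is.null(rep_ids)) rep_ids <- paste0("r", seq_len(ncol(n)))
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in gene ", gene_id)
  if (anyDuplicated(rep_ids)) stop("duplicate replicate ids in gene ", gene_id)

  yo <- y[observed]
  no <- n[observed]
  if (any(!is.finite(yo)) || any(!is.finite(no)))
    stop("non-finite counts in observed cells of gene ", gene_id)
  if (any(yo < 0) || any(no < 0))
    stop("negative counts in gene ", gene_id)
  if (any(yo > no))
    stop("y exceeds n in gene ", gene_id)
  y[!observed] <- NA_real_
  n[!observed] <- NA_real_
  dimnames(y) <- dimnames(n) <- dimnames(observed) <-
    list(snp_ids, rep_ids)

  structure(
    list(gene_id = as.character(gene_id), snp_ids = as.character(snp_ids),
         rep_ids = as.character(rep_ids), y = y, n = n, observed = observed),
    class = "ase_counts")
}

#' @export
print.ase_counts <- function(x, ...) {
  cat(sprintf("<ase_counts> gene %s: %d SNP(s) x %d replicate(s), %d/%d cells observed\n",
              x$gene_id, nrow(x$n), ncol(x$n), sum(x$observed),
              length(x$observed)))
  invisible(x)
}

#' A collection of genes
#'
#' @param genes list of [ase_counts()] objects with unique gene ids.
#' @param provenance free-text metadata (source file, tissue, seed, ...).
#' @return an object of class `"ase_dataset"`: a list with elements `genes`
#'   (named by gene id) and `provenance`.
#' @export
ase_dataset <- function(genes, provenance = character()) {
  stopifnot(all(vapply(genes, inherits, logical(1), "ase_counts")))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  names(genes) <- ids
  structure(list(genes = genes, provenance = provenance),
            class = "ase_dataset")
}

#' @export
print.ase_dataset <- function(x, ...) {
  cat(sprintf("<ase_dataset> %d gene(s)\n", length(x$genes)))
  if (length(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.ase_dataset <- function(x) length(x$genes)

#' Read an allele-resolved count table
#'
#' Long-format TSV with header columns `gene`, `snp`, `replicate`, `y`, `n`
#' and one row per observed (gene, SNP, replicate) cell; lines starting with
#' `#` are ignored.  SNP order within a gene is first-appearance (file)
#' order, documented as genomic order by convention; the package never
#' re-sorts by coordinate.
#'
#' @param path file path.
#' @param format only `"long-tsv"` is supported.
#' @return an [ase_dataset()].
#' @export
read_ase_counts <- function(path, format = "long-tsv") {
  format <- match.arg(format, "long-tsv")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  required <- c("gene", "snp", "replicate", "y", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  dataset_from_long(df, provenance = paste("file:", path))
}

#' Build a dataset from a long-format data frame
#'
#' @param df data frame with columns `gene`, `snp`, `replicate`, `y`, `n`.
#' @param provenance free-text metadata.
#' @return an [ase_dataset()].
#' @export
dataset_from_long <- function(df, provenance = character()) {
  if (any(df$y < 0 | df$n < 0)) stop("negative counts")
  if (any(df$y > df$n)) stop("y exceeds n")
  key <- paste(df$gene, df$snp, df$replicate, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (gene, snp, replicate) cells")

  genes <- lapply(split(df, factor(df$gene, levels = unique(df$gene))),
                  function(sub) {
    snp_ids <- unique(sub$snp)
    rep_ids <- unique(sub$replicate)
    J <- length(snp_ids); K <- length(rep_ids)
    y <- matrix(NA_real_, J, K, dimnames = list(snp_ids, rep_ids))
    n <- y
    ji <- match(sub$snp, snp_ids)
    ki <- match(sub$replicate, rep_ids)
    y[cbind(ji, ki)] <- sub$y
    n[cbind(ji, ki)] <- sub$n
    ase_counts(sub$gene[[1L]], y, n, snp_ids, rep_ids)
  })
  ase_dataset(unname(genes), provenance = provenance)
}

#' Write a dataset as a long-format count table
#'
#' Inverse of [read_ase_counts()]: `read_ase_counts(write_ase_counts(ds, f))`
#' reproduces `ds` cell for cell.
#'
#' @param ds an [ase_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ase_counts <- function(ds, path) {
  rows <- lapply(ds$genes, function(g) {
    idx <- which(g$observed, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(gene = g$gene_id,
               snp = g$snp_ids[idx[, 1L]],
               replicate = g$rep_ids[idx[, 2L]],
               y = g$y[idx], n = g$n[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ratio constancy by exact cross-multiplication (no floating-point division):
# all observed y/n equal  <=>  y_i * n_1 == y_1 * n_i for every cell i
all_ratios_equal <- function(y, n) {
  stopifnot(length(y) == length(n), length(y) >= 1L)
  y <- as.numeric(y); n <- as.numeric(n)
  all(y * n[[1L]] == y[[1L]] * n)
}

#' Filter genes before model fitting
#'
#' Applies the standard usability rules for allele-resolved count tables:
#' SNPs observed in fewer than two replicates are dropped from the gene
#' (single-replicate SNPs cannot inform replicate-level variation), then a
#' gene is removed when
#' (a) it had fewer than two SNPs to begin with,
#' (b) fewer than two usable SNPs remain after the drop, or
#' (c) the observed maternal fractions \eqn{y/n} are identical across all
#'     observed cells (constancy checked by exact cross-multiplication, so
#'     e.g. 1/2 and 5/10 compare equal) — inference is trivial there.
#'
#' @param ds an [ase_dataset()].
#' @return list with elements `dataset` (retained genes, possibly with SNPs
#'   dropped) and `report`, a data frame of per-rule removal counts with
#'   rules `a` (single-SNP gene), `b` (SNPs not shared by two replicates)
#'   and `c` (constant allelic ratio).
#' @export
filter_genes <- function(ds) {
  removed <- c(a = 0L, b = 0L, c = 0L)
  kept <- list()
  for (g in ds$genes) {
    if (length(g$snp_ids) < 2L) {
      removed[["a"]] <- removed[["a"]] + 1L
      next
    }
    usable <- rowSums(g$observed) >= 2L
    if (sum(usable) < 2L) {
      removed[["b"]] <- removed[["b"]] + 1L
      next
    }
    g2 <- if (all(usable)) g else
      ase_counts(g$gene_id, g$y[usable, , drop = FALSE],
                 g$n[usable, , drop = FALSE],
                 g$snp_ids[usable], g$rep_ids)
    if (all_ratios_equal(g2$y[g2$observed], g2$n[g2$observed])) {
      removed[["c"]] <- removed[["c"]] + 1L
      next
    }
    kept[[length(kept) + 1L]] <- g2
  }
  list(dataset = ase_dataset(kept, provenance = ds$provenance),
       report = data.frame(rule = names(removed),
                           removed = as.integer(removed),
                           stringsAsFactors = FALSE))
}
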