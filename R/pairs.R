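#' Enumerate all unordered gene pairs
#'
#' Every gene is paired with every other gene exactly once, oriented
#' `(gene_a, gene_b)` with `gene_a` preceding `gene_b` in the input order.
#' The reversed orientation is the indicator complement and carries no extra
#' information, so only one orientation is kept. With `n` genes this yields
#' `n * (n - 1) / 2` pairs, deterministically ordered.
#'
#' @param gene_ids Character vector of >= 2 unique gene identifiers.
#' @return A `data.frame` with columns `gene_a`, `gene_b`.
#' @export
enumerate_pairs <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  n <- length(gene_ids)
  if (n < 2L) stop("need at least 2 genes to form pairs")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(gene_a = gene_ids[i], gene_b = gene_ids[j], stringsAsFactors = FALSE)
}

pair_ids <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "|")

#' Compute within-sample pair-ordering indicators
#'
#' For each pair and sample the indicator is 1 when the first gene's
#' expression strictly exceeds the second's in that sample, and 0 otherwise
#' (ties score 0, as does the reversed order). The result depends only on the
#' within-sample ranking, so it is invariant under any strictly increasing
#' per-sample transform of the expression values — the property that lets a
#' signature built on one platform score another without normalization.
#'
#' @param m Genes-x-samples numeric matrix.
#' @param pairs `data.frame` with `gene_a`, `gene_b` columns, as from
#'   [enumerate_pairs()].
#' @return Integer 0/1 matrix, pairs x samples, rownames `"GENEA|GENEB"`.
#' @export
compute_indicators <- function(m, pairs) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  absent <- setdiff(genes, rownames(m))
  if (length(absent) > 0L) {
    stop("pair gene(s) absent from expression matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  im <- (m[pairs$gene_a, , drop = FALSE] > m[pairs$gene_b, , drop = FALSE]) + 0L
  storage.mode(im) <- "integer"
  rownames(im) <- pair_ids(pairs)
  im
}

#' Remove near-constant pair indicators
#'
#' A pair is dropped when its indicator takes the same value (0 or 1) in
#' strictly more than `threshold` of the samples; a pair constant in exactly
#' `threshold` of samples is kept ("more than" is strict). Pairs surviving
#' the filter keep their original order.
#'
#' @param im Pairs-x-samples 0/1 indicator matrix.
#' @param threshold Constancy fraction in (0, 1); default 0.80.
#' @return The filtered indicator matrix (possibly 0 rows).
#' @export
filter_constant_pairs <- function(im, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  if (ncol(im) < 1L) stop("indicator matrix has no samples")
  f1 <- rowMeans(im)
  keep <- pmax(f1, 1 - f1) <= threshold
  im[keep, , drop = FALSE]
}

#' Enumerate, score and filter pairs in chunks
#'
#' Builds the filtered indicator matrix without ever materializing the full
#' pairs-x-samples matrix: pairs are scored in chunks and only rows passing
#' the constancy filter are retained. With thousands of genes the full pair
#' space runs to millions of rows while a few percent survive the filter, so
#' the peak memory is `chunk_size` x samples.
#'
#' @param m Genes-x-samples matrix.
#' @param pairs Optional pair `data.frame`; defaults to all pairs of
#'   `rownames(m)`.
#' @param threshold Constancy threshold passed to [filter_constant_pairs()].
#' @param chunk_size Pairs scored per chunk.
#' @return Filtered 0/1 indicator matrix.
#' @export
build_filtered_indicators <- function(m, pairs = NULL, threshold = 0.80,
                                      chunk_size = 100000L) {
  if (is.null(pairs)) pairs <- enumerate_pairs(rownames(m))
  n <- nrow(pairs)
  starts <- seq(1L, n, by = chunk_size)
  kept <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + chunk_size - 1L, n)
    im <- compute_indicators(m, pairs[idx, , drop = FALSE])
    kept[[k]] <- filter_constant_pairs(im, threshold)
  }
  out <- do.call(rbind, kept)
  if (is.null(out)) out <- matrix(integer(0), 0L, ncol(m), dimnames = list(NULL, colnames(m)))
  out
}

#' Split `"GENEA|GENEB"` pair ids back into gene columns
#'
#' @param ids Character vector of pair ids.
#' @return `data.frame` with `gene_a`, `gene_b`.
#' @export
split_pair_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed pair id(s): ", paste(utils::head(ids[bad], 5L), collapse = ", "))
  data.frame(
    gene_a = vapply(parts, `[[`, character(1L), 1L),
    gene_b = vapply(parts, `[[`, character(1L), 2L),
    stringsAsFactors = FALSE
  )
}
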