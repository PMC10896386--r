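# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.key <- function(contig, pos) paste(contig, pos, sep = ":")

DNA_BASES4 <- c("A", "C", "G", "T")

.comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.comp <- function(x) unname(.comp_map[x])

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# largest-remainder apportionment of n items to proportions p (sums to n)
.quota_counts <- function(p, n) {
  .assert(abs(sum(p) - 1) < 1e-9, "proportions must sum to 1")
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Tile contigs into fixed-width genomic windows
#'
#' @param contigs named integer vector of contig lengths.
#' @param width window width in base pairs.
#' @return data.frame with columns `contig`, `start`, `end` (1-based,
#'   inclusive); the last window of each contig is truncated at the contig
#'   end.
#' @export
tile_windows <- function(contigs, width) {
  .assert(width >= 1, "window width must be >= 1")
  out <- lapply(names(contigs), function(ct) {
    len <- contigs[[ct]]
    start <- seq(1L, len, by = as.integer(width))
    data.frame(contig = ct, start = start,
               end = pmin(start + as.integer(width) - 1L, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
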