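#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices for the 20 standard amino acids,
#' spanning -4.5 (Arg) to +4.5 (Ile).  The scale span (9) is the
#' normalisation constant of the complementarity degree; no residue has
#' index exactly 0, so every residue carries a well-defined hydropathy
#' sign.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @export
#' @examples
#' kyte_doolittle()["I"]  # 4.5
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Span of the hydropathy scale
#'
#' max - min of the Kyte-Doolittle scale (4.5 - (-4.5) = 9), the
#' denominator constant of [complementarity_degree()].
#' @return 9
#' @export
hydropathy_span <- function() 9

# split a sequence string into validated single-letter residues;
# non-standard letters (B, J, O, U, X, Z, ...) are an error because
# silently skipping them would change the window length L and hence C.
.residues <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L) return(character(0))
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(kyte_doolittle()))
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d", res[bad[1]], bad[1]),
         call. = FALSE)
  res
}

#' Binary hydrophobicity map of a sequence
#'
#' Converts a protein sequence into its signed (+/-) hydrophobicity map
#' and the underlying raw Kyte-Doolittle indices.
#'
#' @param sequence Character string over the 20 standard one-letter codes.
#' @return List with `signs` (integer +1/-1 per residue) and `index`
#'   (numeric hydropathy per residue).
#' @export
#' @examples
#' hydropathy_map("IR")  # signs +1, -1; index 4.5, -4.5
hydropathy_map <- function(sequence) {
  res <- .residues(sequence)
  idx <- unname(kyte_doolittle()[res])
  list(signs = as.integer(sign(idx)), index = idx)
}

#' Percent match between two hydropathy sign vectors
#'
#' Fraction (as a percentage) of aligned positions whose hydropathy
#' signs are opposite, i.e. complementary (+/-) pairs over all matched
#' pairs.
#'
#' @param motif_signs,window_signs Equal-length sign vectors (+1/-1), as
#'   produced by [hydropathy_map()].
#' @return Percentage in \[0, 100\].
#' @export
percent_match <- function(motif_signs, window_signs) {
  if (length(motif_signs) != length(window_signs))
    stop("sign vectors must have equal length", call. = FALSE)
  if (length(motif_signs) == 0L) stop("empty sign vectors", call. = FALSE)
  100 * sum(motif_signs * window_signs < 0) / length(motif_signs)
}

#' Degree of complementary hydropathy
#'
#' The complementarity score
#' \deqn{C = \sum_{i=1}^{L} |H(i) - H'(i)| / (9 L)}
#' where H and H' are the Kyte-Doolittle indices of the two aligned
#' sequences and 9 is the scale span.  C ranges from 0 (identical
#' hydropathy) to 1 (Ile/Arg pairing at every position).
#'
#' @param motif_index,window_index Equal-length numeric hydropathy vectors.
#' @return C in \[0, 1\].
#' @export
#' @examples
#' complementarity_degree(hydropathy_map("II")$index,
#'                        hydropathy_map("RR")$index)  # 1
complementarity_degree <- function(motif_index, window_index) {
  if (length(motif_index) != length(window_index))
    stop("index vectors must have equal length", call. = FALSE)
  L <- length(motif_index)
  if (L < 1L) stop("need length >= 1", call. = FALSE)
  sum(abs(motif_index - window_index)) / (L * hydropathy_span())
}

#' Screen a motif against a target by complementary hydropathy
#'
#' Slides the motif in both forward and reverse residue order across
#' every window of the target (step 1) and scores each alignment with
#' [percent_match()] and [complementarity_degree()].  A hit passes when
#' percent match exceeds 75 and the complementarity degree exceeds 0.5
#' (both strict, per the screen's published rule).
#'
#' @param motif Motif sequence (string), length >= 3, or a `bli_motif`
#'   from [motif()].
#' @param target Target sequence (string), at least as long as the motif.
#' @param pm_threshold,degree_threshold Pass thresholds (strict `>`).
#' @return data.frame with one row per (orientation, window): columns
#'   `motif`, `orientation`, `window_start`, `window_end`,
#'   `percent_match`, `degree`, `passes`.
#' @export
screen <- function(motif, target, pm_threshold = 75, degree_threshold = 0.5) {
  name <- "motif"
  if (inherits(motif, "bli_motif")) {
    name <- motif$name
    motif <- motif$sequence
  }
  mres <- .residues(motif)
  tmap <- hydropathy_map(target)
  L <- length(mres)
  n <- length(tmap$index)
  if (L < 1L) stop("empty motif", call. = FALSE)
  if (L > n) stop("motif longer than target", call. = FALSE)
  mmap <- hydropathy_map(motif)
  nw <- n - L + 1L
  out <- vector("list", 2L)
  for (k in 1:2) {
    orient <- c("forward", "reverse")[k]
    mi <- if (k == 1L) mmap$index else rev(mmap$index)
    ms <- if (k == 1L) mmap$signs else rev(mmap$signs)
    pm <- numeric(nw); dg <- numeric(nw)
    for (s in seq_len(nw)) {
      w <- s:(s + L - 1L)
      pm[s] <- 100 * sum(ms * tmap$signs[w] < 0) / L
      dg[s] <- sum(abs(mi - tmap$index[w])) / (L * hydropathy_span())
    }
    out[[k]] <- data.frame(
      motif = name, orientation = orient,
      window_start = seq_len(nw), window_end = seq_len(nw) + L - 1L,
      percent_match = pm, degree = dg,
      passes = pm > pm_threshold & dg > degree_threshold,
      stringsAsFactors = FALSE)
  }
  rbind(out[[1]], out[[2]])
}

#' Construct a named motif with source-region annotation
#'
#' @param name Motif label (e.g. "CDR2" or "helix5").
#' @param sequence Residues (length >= 3).
#' @param protein,start,end Optional source region (1-based inclusive);
#'   when given, `end - start + 1` must equal the sequence length.
#' @return `bli_motif` object.
#' @export
motif <- function(name, sequence, protein = NA_character_,
                  start = NA_integer_, end = NA_integer_) {
  res <- .residues(sequence)
  if (length(res) < 3L) stop("motif must have length >= 3", call. = FALSE)
  if (!is.na(start) && !is.na(end) && (end - start + 1L) != length(res))
    stop("region length does not match sequence length", call. = FALSE)
  structure(list(name = name, sequence = paste(res, collapse = ""),
                 protein = protein, start = start, end = end),
            class = "bli_motif")
}

#' Screen a motif set and summarise hits into candidate binding regions
#'
#' Runs [screen()] for every motif (both orientations), accumulates
#' per-residue counts of passing-hit coverage on the target, and merges
#' passing windows that overlap or abut (gap <= 1 residue) into
#' candidate regions.
#'
#' @param motifs List of `bli_motif` objects (or plain strings).
#' @param target Target sequence.
#' @param offset 1-based position of the first target residue within the
#'   full-length protein (so reported coordinates can be in full-protein
#'   numbering); default 1.
#' @param ... Passed to [screen()].
#' @return List with `hits` (all windows), `counts` (per-residue passing
#'   coverage, length = nchar(target)), and `regions` (data.frame of
#'   merged passing regions with `start`, `end`, `n_hits`).
#' @export
screen_region_set <- function(motifs, target, offset = 1L, ...) {
  if (!is.list(motifs)) motifs <- list(motifs)
  hits <- do.call(rbind, lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    h <- screen(m, target, ...)
    if (!inherits(m, "bli_motif") && !is.null(names(motifs)[i]) &&
        !is.na(names(motifs)[i]) && nzchar(names(motifs)[i]))
      h$motif <- names(motifs)[i]
    h
  }))
  n <- nchar(target)
  counts <- integer(n)
  pass <- hits[hits$passes, , drop = FALSE]
  for (r in seq_len(nrow(pass)))
    counts[pass$window_start[r]:pass$window_end[r]] <-
      counts[pass$window_start[r]:pass$window_end[r]] + 1L
  regions <- merge_windows(pass$window_start, pass$window_end, gap = 1L)
  if (nrow(regions)) {
    regions$n_hits <- vapply(seq_len(nrow(regions)), function(i)
      sum(pass$window_start <= regions$end[i] &
          pass$window_end >= regions$start[i]), integer(1))
    regions$start <- regions$start + offset - 1L
    regions$end <- regions$end + offset - 1L
  } else regions$n_hits <- integer(0)
  hits$window_start <- hits$window_start + offset - 1L
  hits$window_end <- hits$window_end + offset - 1L
  list(hits = hits, counts = counts, regions = regions)
}

#' Merge integer intervals that overlap or abut
#'
#' @param start,end Equal-length integer vectors (1-based inclusive).
#' @param gap Maximum separation regarded as contiguous (default 1:
#'   abutting windows merge).
#' @return data.frame `start`, `end`, sorted, non-overlapping.
#' @export
merge_windows <- function(start, end, gap = 1L) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

#' Write a hits table to TSV
#' @param hits data.frame from [screen()] or `screen_region_set()$hits`.
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
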