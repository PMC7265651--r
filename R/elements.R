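## degenerate base sets for element patterns (W = A/T, R = A/G)
.iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                    W = c("A", "T"), R = c("A", "G"))

## mismatch count of `s` (same length) against a degenerate pattern
pattern_mismatches <- function(s, pattern) {
  sb <- strsplit(s, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  sum(vapply(seq_along(pb), function(i) {
    !(sb[i] %in% .iupac_sets[[pb[i]]])
  }, logical(1)))
}

#' Scan a promoter window for core-promoter elements
#'
#' Element classes: `tata_consensus` — exact TATAWAWR (W = A/T,
#' R = A/G; degenerate positions match their base sets at zero cost);
#' `tata_like` — TATAWAWR with 1 or 2 mismatches (exact-consensus hits
#' are excluded so the classes stay disjoint); `gae` — the GA-rich
#' element, exact GAAAAA. Hits are searched on the promoter strand;
#' offsets are relative to the window anchor; overlapping hits are all
#' reported.
#'
#' @param genome Named character vector of sequences.
#' @param window One row of a `promoter_windows` table.
#' @param element_kind One of `"tata_consensus"`, `"tata_like"`,
#'   `"gae"`.
#' @return data.frame with `offset` (element start, promoter-relative)
#'   and `mismatches`; empty when the window is shorter than the
#'   element.
#' @export
scan_elements <- function(genome, window,
                          element_kind = c("tata_consensus", "tata_like",
                                           "gae")) {
  element_kind <- match.arg(element_kind)
  pattern <- if (element_kind == "gae") "GAAAAA" else "TATAWAWR"
  mm_range <- switch(element_kind, tata_consensus = 0L, gae = 0L,
                     tata_like = c(1L, 2L))
  rel <- window_rel_coords(window, 1L)
  ch <- oriented_chars(genome, window$chrom, window$anchor_pos,
                       window$strand, min(rel), max(rel))
  pb <- strsplit(pattern, "")[[1]]
  L <- length(pb)
  n <- length(ch)
  if (n < L)
    return(data.frame(offset = integer(0), mismatches = integer(0)))
  ## vectorized mismatch count: one pass per pattern position
  mm <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    b <- ch[j:(n - L + j)]
    mm <- mm + as.integer(is.na(b) | !b %in% .iupac_sets[[pb[j]]])
  }
  keep <- if (length(mm_range) == 1) mm == mm_range else
    mm >= mm_range[1] & mm <= mm_range[2]
  data.frame(offset = rel[which(keep)], mismatches = mm[keep])
}

#' Element presence per promoter in a search region
#'
#' @param genome Named character vector of sequences.
#' @param windows A `promoter_windows` table (typically median-TSS
#'   anchored).
#' @param element_kind Passed to [scan_elements()].
#' @param region Offset range searched, relative to the anchor
#'   (default `c(-200, 0)`; functional elements sit ~50-100 bp
#'   upstream of the TSS cluster).
#' @return Logical vector: promoter has at least one hit starting in
#'   the region.
#' @export
element_presence <- function(genome, windows, element_kind,
                             region = c(-200L, 0L)) {
  vapply(seq_len(nrow(windows)), function(i) {
    h <- scan_elements(genome, windows[i, ], element_kind)
    any(h$offset >= region[1] & h$offset <= region[2])
  }, logical(1))
}

#' Element enrichment by promoter class and expression decile
#'
#' Fraction of promoters carrying at least one element hit, per
#' (class, decile) cell; presence/absence, overlapping hits are not
#' merged or double counted.
#'
#' @param has_element Logical per-promoter presence vector
#'   ([element_presence()]).
#' @param deciles Integer decile labels ([expression_deciles()]).
#' @param classes Promoter class labels.
#' @return data.frame with `promoter_class`, `decile`, `n`,
#'   `fraction` (NA for empty cells).
#' @export
element_enrichment_by_decile <- function(has_element, deciles, classes) {
  grid <- expand.grid(promoter_class = sort(unique(classes)),
                      decile = sort(unique(deciles)),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(cl, de) sum(classes == cl & deciles == de),
                   grid$promoter_class, grid$decile)
  grid$fraction <- mapply(function(cl, de) {
    idx <- classes == cl & deciles == de
    if (!any(idx)) NA_real_ else mean(has_element[idx])
  }, grid$promoter_class, grid$decile)
  grid
}
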