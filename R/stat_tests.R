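#' Dunn's post hoc pairwise test on rank sums
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis ranking over
#' all groups, with the standard tie correction
#' `sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values.
#'
#' @param values Numeric observations.
#' @param groups Group labels (factor or character).
#' @param control Level compared against every other level.
#' @return data.frame with `group`, `z`, `p` for each non-control level.
#' @export
dunn_posthoc <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(control %in% groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(r, groups, mean)
  n_g <- table(groups)
  others <- setdiff(names(mean_rank), control)
  z <- vapply(others, function(g) {
    se <- sqrt(s2 * (1 / n_g[[g]] + 1 / n_g[[control]]))
    if (se == 0) return(0)
    (mean_rank[[g]] - mean_rank[[control]]) / se
  }, numeric(1))
  data.frame(group = others, z = unname(z),
             p = 2 * stats::pnorm(-abs(unname(z))))
}

## read-level positional observations for one promoter in one library,
## capped by seeded subsampling (KW/Dunn input size is unbounded
## otherwise)
.positional_obs <- function(signal, window, cap, seed) {
  d <- window_counts(signal, window)
  obs <- rep.int(d$rel, d$counts)
  if (length(obs) > cap)
    obs <- with_seed(seed, sample(obs, cap))
  obs
}

#' Per-promoter shift significance tests across libraries
#'
#' Each read is one observation of its TSS position. Per promoter:
#' a Kruskal-Wallis test across all libraries (each replicate library
#' its own group) asks whether any library's positional distribution
#' differs; Dunn's post hoc test compares each mutant strain against
#' WT (replicates pooled per strain, ranked over all strains), with BH
#' adjustment across promoters within each contrast; a Mann-Whitney U
#' test on the same pooled positional samples is added for strains
#' where both sides have at least 3 replicates.
#'
#' @param signals_by_strain Named list; each element a list of
#'   replicate `stranded_signal`s for one strain.
#' @param windows WT-anchored `promoter_windows`.
#' @param wt_label Name of the WT strain in `signals_by_strain`.
#' @param cap Per-promoter per-library observation cap (default 5000,
#'   seeded subsampling).
#' @param seed Integer seed for the subsampling.
#' @param mwu_level `"read"` (default) uses read-level positions;
#'   `"replicate"` uses per-replicate median TSS positions as the
#'   observations.
#' @return data.frame with one row per promoter x mutant strain:
#'   `promoter_id`, `strain`, `kw_p`, `dunn_p`, `dunn_adj`, `mwu_p`,
#'   `mwu_adj`, `skipped`.
#' @export
promoter_shift_tests <- function(signals_by_strain, windows, wt_label,
                                 cap = 5000L, seed = 1L,
                                 mwu_level = c("read", "replicate")) {
  mwu_level <- match.arg(mwu_level)
  stopifnot(wt_label %in% names(signals_by_strain))
  strains <- names(signals_by_strain)
  muts <- setdiff(strains, wt_label)
  n_rep <- vapply(signals_by_strain, length, integer(1))
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    ## observations per library and pooled per strain
    lib_obs <- list(); strain_obs <- list()
    for (s in strains) {
      reps <- signals_by_strain[[s]]
      ob <- lapply(seq_along(reps), function(j)
        .positional_obs(reps[[j]], w,
                        cap, substream_seed(seed, paste0(s, j, i))))
      names(ob) <- paste0(s, ".", seq_along(reps))
      lib_obs <- c(lib_obs, ob)
      strain_obs[[s]] <- unlist(ob, use.names = FALSE)
    }
    nonempty <- lib_obs[lengths(lib_obs) > 0]
    pooled <- unlist(nonempty, use.names = FALSE)
    degenerate <- length(nonempty) < 2 || length(unique(pooled)) < 2
    kw_p <- NA_real_
    if (!degenerate) {
      g <- rep(names(nonempty), lengths(nonempty))
      kw_p <- stats::kruskal.test(pooled, factor(g))$p.value
    }
    for (m in muts) {
      dunn_p <- mwu_p <- NA_real_
      skipped <- degenerate || !length(strain_obs[[m]]) ||
        !length(strain_obs[[wt_label]])
      if (!skipped) {
        v <- c(strain_obs[[m]], strain_obs[[wt_label]])
        gg <- rep(c(m, wt_label), c(length(strain_obs[[m]]),
                                    length(strain_obs[[wt_label]])))
        if (length(unique(v)) >= 2) {
          ## rank over all strains so Dunn uses the KW-style pooled ranking
          va <- unlist(strain_obs, use.names = FALSE)
          ga <- rep(names(strain_obs), lengths(strain_obs))
          dunn_p <- dunn_posthoc(va, ga, wt_label)
          dunn_p <- dunn_p$p[dunn_p$group == m]
          if (n_rep[[m]] >= 3 && n_rep[[wt_label]] >= 3) {
            if (mwu_level == "read") {
              mwu_p <- stats::wilcox.test(strain_obs[[m]],
                                          strain_obs[[wt_label]],
                                          exact = FALSE)$p.value
            } else {
              med_m <- vapply(signals_by_strain[[m]], function(sg)
                as.numeric(median_tss(window_counts(sg, w))), numeric(1))
              med_w <- vapply(signals_by_strain[[wt_label]], function(sg)
                as.numeric(median_tss(window_counts(sg, w))), numeric(1))
              mwu_p <- tryCatch(stats::wilcox.test(med_m, med_w,
                                                   exact = FALSE)$p.value,
                                error = function(e) NA_real_)
            }
          }
        } else skipped <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_id = w$promoter_id, strain = m, kw_p = kw_p,
        dunn_p = dunn_p, mwu_p = mwu_p, skipped = skipped)
    }
  }
  out <- do.call(rbind, rows)
  out$dunn_adj <- NA_real_
  out$mwu_adj <- NA_real_
  for (m in muts) {
    idx <- out$strain == m
    out$dunn_adj[idx] <- stats::p.adjust(out$dunn_p[idx], method = "BH")
    out$mwu_adj[idx] <- stats::p.adjust(out$mwu_p[idx], method = "BH")
  }
  out
}
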