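# Cross-method comparison of stability changes: experimental ddG from
# melting-temperature shifts versus computed ddG from MM-PBSA, plus the
# end-to-end pipeline report.

#' Correlate experimental and computed delta-delta-G values
#'
#' Pairs variants by label (order independent) and reports the Pearson
#' correlation with least-squares slope/intercept, and the Spearman rank
#' correlation as a robustness secondary. The two methods use opposite sign
#' conventions by default (TDTF: destabilized variants are negative;
#' MM-PBSA: destabilized variants are positive), so both vectors are first
#' oriented so that larger means more destabilized.
#'
#' @param tdtf named numeric vector of ddG_TDTF per variant (kcal/mol).
#' @param mmpbsa named numeric vector of ddG_MM-PBSA per variant (kcal/mol).
#' @param tdtf_destabilizing,mmpbsa_destabilizing sign carried by a
#'   destabilized variant under each convention (`"negative"`/`"positive"`).
#' @return object of class `ddg_correlation`: `r` (Pearson), `slope`,
#'   `intercept`, `spearman`, `n`, `variants`, and the reconciled vectors
#'   `x` (TDTF) and `y` (MM-PBSA).
#' @export
correlate_ddg <- function(tdtf, mmpbsa,
                          tdtf_destabilizing = c("negative", "positive"),
                          mmpbsa_destabilizing = c("positive", "negative")) {
  tdtf_destabilizing <- match.arg(tdtf_destabilizing)
  mmpbsa_destabilizing <- match.arg(mmpbsa_destabilizing)
  if (is.null(names(tdtf)) || is.null(names(mmpbsa)))
    stop("both ddG vectors must be named by variant")
  shared <- intersect(names(tdtf), names(mmpbsa))
  if (length(shared) < 3L)
    stop("insufficient data: need >= 3 shared variants, have ", length(shared))
  x <- as.numeric(tdtf[shared]) * if (tdtf_destabilizing == "negative") -1 else 1
  y <- as.numeric(mmpbsa[shared]) * if (mmpbsa_destabilizing == "negative") -1 else 1
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in one of the ddG vectors")
  r <- stats::cor(x, y)
  co <- stats::coef(stats::lm(y ~ x))
  structure(list(r = r, slope = unname(co[2L]), intercept = unname(co[1L]),
                 spearman = stats::cor(x, y, method = "spearman"),
                 n = length(shared), variants = shared, x = x, y = y),
            class = "ddg_correlation")
}

#' @export
print.ddg_correlation <- function(x, ...) {
  cat(sprintf("ddg_correlation: Pearson r = %.3f (Spearman %.3f), n = %d, y = %.3f x %+.3f\n",
              x$r, x$spearman, x$n, x$slope, x$intercept))
  invisible(x)
}

.report_table <- function(df, digits = 4) {
  df2 <- df
  for (j in seq_along(df2)) if (is.numeric(df2[[j]]))
    df2[[j]] <- formatC(df2[[j]], digits = digits, format = "g")
  c(paste(names(df2), collapse = "\t"),
    do.call(paste, c(unname(as.list(df2)), sep = "\t")))
}

#' End-to-end pipeline report
#'
#' Collects whatever stage outputs were produced into one structured,
#' deterministic text report (byte-for-byte identical given identical inputs
#' and settings): per-stage tables, parameter echoes, seeds and the tool
#' version. Stages not supplied are omitted without error.
#'
#' @param stages named list; recognized names: `rmsd` (an `rmsd_series` or
#'   list of them), `rmsd_distribution`, `rmsf` (an `rmsf_profile`),
#'   `width_variance` (a `width_variance` or list), `clusters`
#'   (`cluster_assignment`), `mmpbsa` (a `ddg_table`), `pmf` (`pmf_profile`
#'   or list), `wetlab` (list of fit objects), `correlation`
#'   (`ddg_correlation` or list).
#' @param seed seed echoed into the header (optional).
#' @param params named list of parameters echoed into the header.
#' @param file optional output path.
#' @return character vector of report lines, invisibly.
#' @export
pipeline_report <- function(stages, seed = NULL, params = list(), file = NULL) {
  if (!length(stages)) stop("at least one stage output must be supplied")
  L <- c("= groovedyn pipeline report =",
         sprintf("version: %s", as.character(utils::packageVersion("groovedyn"))))
  if (!is.null(seed)) L <- c(L, sprintf("seed: %s", format(seed)))
  if (length(params))
    L <- c(L, sprintf("parameters: %s",
                      paste(names(params), vapply(params, function(p)
                        paste(format(p), collapse = ","), character(1)),
                        sep = "=", collapse = " ")))
  sec <- function(title, lines) c("", paste0("== ", title, " =="), lines)
  as_list <- function(x, cls) if (inherits(x, cls)) list(x) else x
  s <- stages
  if (!is.null(s$rmsd)) {
    xs <- as_list(s$rmsd, "rmsd_series")
    lines <- unlist(lapply(seq_along(xs), function(i)
      sprintf("series %s: %d frames, mean %.3f A, max %.3f A",
              names(xs)[i] %||% i, length(xs[[i]]$values),
              mean(xs[[i]]$values), max(xs[[i]]$values))))
    L <- c(L, sec("RMSD series", lines))
  }
  if (!is.null(s$rmsd_distribution)) {
    d <- s$rmsd_distribution
    L <- c(L, sec("RMSD distribution",
                  sprintf("modes (A): %s",
                          paste(formatC(d$modes, digits = 3, format = "f"),
                                collapse = ", "))))
  }
  if (!is.null(s$rmsf)) {
    p <- s$rmsf
    L <- c(L, sec("RMSF profile",
                  c(sprintf("%d residues, mean %.3f A, max %.3f A (residue %d)",
                            nrow(p), mean(p$rmsf), max(p$rmsf),
                            p$resno[which.max(p$rmsf)]))))
  }
  if (!is.null(s$width_variance)) {
    xs <- as_list(s$width_variance, "width_variance")
    lines <- vapply(xs, function(w)
      sprintf("region %s: mean width %.2f A, WV %.4f A^2",
              w$region, w$mean_width, w$wv), character(1))
    L <- c(L, sec("Groove width variance", lines))
  }
  if (!is.null(s$clusters)) {
    cl <- s$clusters
    L <- c(L, sec("Leader clustering",
                  sprintf("%d clusters at cutoff %.2f A over %d frames",
                          length(cl$representatives), cl$cutoff,
                          length(cl$labels))))
  }
  if (!is.null(s$mmpbsa)) {
    L <- c(L, sec("MM-PBSA ddG ranking", .report_table(as.data.frame(s$mmpbsa))))
  }
  if (!is.null(s$pmf)) {
    xs <- as_list(s$pmf, "pmf_profile")
    lines <- unlist(lapply(seq_along(xs), function(i) {
      p <- xs[[i]]
      sprintf("profile %s: %d bins, barrier %.2f kcal/mol, %s",
              names(xs)[i] %||% i, sum(!is.na(p$W)),
              max(p$W, na.rm = TRUE),
              if (p$converged) "converged" else "not converged")
    }))
    L <- c(L, sec("Potential of mean force", lines))
  }
  if (!is.null(s$wetlab)) {
    lines <- unlist(lapply(names(s$wetlab), function(nm) {
      f <- s$wetlab[[nm]]
      if (inherits(f, "melting_fit"))
        sprintf("%s: Tm = %.2f K (%.2f C), dHm = %.1f kcal/mol", nm, f$Tm, f$Tm_C, f$dHm)
      else if (inherits(f, "ic50_fit"))
        sprintf("%s: IC50 = %.3g M, Hill %.2f", nm, f$ic50, f$hill)
      else if (inherits(f, "decay_fit"))
        sprintf("%s: k = %.4g /min, plateau %.1f%%, t50 = %s min", nm, f$k,
                f$n_inf, if (is.na(f$t50)) "NA" else sprintf("%.1f", f$t50))
      else if (inherits(f, "ddg_tdtf"))
        sprintf("%s: ddG_TDTF = %.2f kcal/mol (dTm = %.2f K)", nm, f$ddG, f$dTm)
      else sprintf("%s: (unrecognized fit object)", nm)
    }))
    L <- c(L, sec("Wet-lab fits", lines))
  }
  if (!is.null(s$correlation)) {
    xs <- as_list(s$correlation, "ddg_correlation")
    lines <- unlist(lapply(seq_along(xs), function(i) {
      co <- xs[[i]]
      sprintf("%s: Pearson r = %.3f, Spearman %.3f, n = %d",
              names(xs)[i] %||% i, co$r, co$spearman, co$n)
    }))
    L <- c(L, sec("Cross-method ddG correlation", lines))
  }
  if (!is.null(file)) writeLines(L, file)
  invisible(L)
}
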