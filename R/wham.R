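# Potential of mean force from umbrella-sampling windows via the weighted
# histogram analysis method (WHAM), plus barrier comparison between profiles.

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872041

#' Construct an umbrella window set
#'
#' @param windows list of windows, each a list with `center` (bias center
#'   xi_0, Angstrom), `k` (harmonic force constant, kcal/mol/Angstrom^2;
#'   the bias is `w(xi) = k/2 (xi - xi_0)^2`), and `samples` (reaction
#'   coordinate values, Angstrom).
#' @param temperature simulation temperature in K.
#' @return object of class `umbrella_windows`.
#' @export
umbrella_window_set <- function(windows, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!all(c("center", "k", "samples") %in% names(w)))
      stop(sprintf("window %d lacks center/k/samples", i))
    if (w$k < 0) stop(sprintf("window %d: force constant must be >= 0", i))
    if (length(w$samples) < 1L) stop(sprintf("window %d has no samples", i))
    if (!all(is.finite(w$samples))) stop(sprintf("window %d: non-finite samples", i))
  }
  structure(list(windows = windows, temperature = temperature),
            class = "umbrella_windows")
}

#' Read umbrella windows from a manifest plus per-window sample files
#'
#' The manifest is a TSV with header `window_id, file, center_A, k_kcal_mol_A2`;
#' each sample file holds one reaction-coordinate value (Angstrom) per line
#' (comment lines `#` ignored). File paths are resolved relative to the
#' manifest's directory.
#'
#' @param manifest path to the manifest TSV.
#' @param temperature temperature in K.
#' @return an [umbrella_window_set()].
#' @export
read_umbrella_windows <- function(manifest, temperature = 300) {
  dir <- dirname(manifest)
  lines <- .as_lines(manifest)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("window_id", "file", "center_A", "k_kcal_mol_A2")
  if (!all(need %in% names(tab)))
    stop("windows manifest must have columns: ", paste(need, collapse = ", "))
  windows <- lapply(seq_len(nrow(tab)), function(i) {
    sl <- readLines(file.path(dir, tab$file[i]), warn = FALSE)
    sl <- sl[!startsWith(sl, "#") & nzchar(trimws(sl))]
    list(center = tab$center_A[i], k = tab$k_kcal_mol_A2[i],
         samples = as.numeric(sl))
  })
  umbrella_window_set(windows, temperature = temperature)
}

#' Write an umbrella window set to a manifest directory
#'
#' @param windows an [umbrella_window_set()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ws <- windows$windows
  files <- sprintf("window_%03d.tsv", seq_along(ws))
  for (i in seq_along(ws)) {
    writeLines(c(.header_comment("umbrella window samples",
                                 list(center = ws[[i]]$center, k = ws[[i]]$k,
                                      temperature = windows$temperature)),
                 format(ws[[i]]$samples, digits = 12, trim = TRUE)),
               file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "windows.tsv")
  writeLines(c(.header_comment("umbrella windows manifest",
                               list(n_windows = length(ws),
                                    temperature = windows$temperature)),
               "window_id\tfile\tcenter_A\tk_kcal_mol_A2",
               sprintf("%d\t%s\t%.10g\t%.10g", seq_along(ws), files,
                       vapply(ws, `[[`, 1, "center"),
                       vapply(ws, `[[`, 1, "k"))),
             manifest)
  invisible(manifest)
}

#' WHAM settings
#'
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @param tolerance convergence tolerance on the window free-energy constants
#'   `f_j` (kcal/mol, default 1e-6).
#' @param max_iter maximum iterations (default 1e5).
#' @param temperature default temperature in K, used when the window set does
#'   not carry one.
#' @return list of settings.
#' @export
wham_settings <- function(bin_width = 0.1, tolerance = 1e-6, max_iter = 1e5,
                          temperature = 300) {
  if (bin_width <= 0 || tolerance <= 0 || max_iter <= 0 || temperature <= 0)
    stop("all WHAM settings must be positive")
  list(bin_width = bin_width, tolerance = tolerance,
       max_iter = as.integer(max_iter), temperature = temperature)
}

#' Solve the WHAM equations for a potential of mean force
#'
#' Iterates the standard self-consistent pair
#' `P(xi_b) = sum_j n_j(xi_b) / sum_j N_j exp(beta f_j - beta w_j(xi_b))` and
#' `exp(-beta f_j) = sum_b P(xi_b) exp(-beta w_j(xi_b))` until
#' `max |delta f_j| < tolerance`, then reports
#' `W(xi) = -k_B T ln P(xi)` anchored so the minimum over populated bins is
#' exactly 0. Bins with zero total counts are reported as `NA` (absent),
#' never interpolated.
#'
#' @param windows an [umbrella_window_set()] (its temperature wins over the
#'   settings default).
#' @param settings a [wham_settings()] list.
#' @return object of class `pmf_profile`: `xi` (bin centers), `W` (kcal/mol,
#'   `NA` on unpopulated bins), `counts`, `temperature`, `converged`,
#'   `iterations`, `f` (window free-energy constants, kcal/mol),
#'   `bin_width`.
#' @export
wham_solve <- function(windows, settings = wham_settings()) {
  stopifnot(inherits(windows, "umbrella_windows"))
  ws <- windows$windows
  temperature <- windows$temperature %||% settings$temperature
  beta <- 1 / (KB_KCAL * temperature)
  bw <- settings$bin_width
  all_xi <- unlist(lapply(ws, `[[`, "samples"))
  lo <- floor(min(all_xi) / bw) * bw
  hi <- ceiling(max(all_xi) / bw) * bw
  breaks <- seq(lo, hi + bw / 2, by = bw)
  centers <- breaks[-length(breaks)] + bw / 2
  J <- length(ws); B <- length(centers)
  njb <- matrix(0, J, B)
  for (j in seq_len(J)) {
    idx <- pmin(pmax(floor((ws[[j]]$samples - lo) / bw) + 1L, 1L), B)
    tb <- tabulate(idx, nbins = B)
    njb[j, ] <- tb
  }
  Nj <- rowSums(njb)
  total <- colSums(njb)
  populated <- total > 0
  if (any(!populated[seq(which.max(populated), B + 1L - which.max(rev(populated)))]))
    warning("gap in sampling: unpopulated bins inside the covered range")
  # bias factors exp(-beta w_j(xi_b))
  Wjb <- t(vapply(ws, function(w) 0.5 * w$k * (centers - w$center)^2,
                  numeric(B)))
  logC <- -beta * Wjb
  f <- rep(0, J)  # in kcal/mol
  converged <- FALSE
  it <- 0L
  delta <- Inf
  logP <- rep(NA_real_, B)
  for (it in seq_len(settings$max_iter)) {
    # log denominator per bin: log sum_j N_j exp(beta f_j + logC[j,b])
    lw <- log(Nj) + beta * f
    M <- lw + logC                       # J x B
    mmax <- apply(M, 2L, max)
    logden <- mmax + log(colSums(exp(sweep(M, 2L, mmax))))
    logP <- ifelse(populated, log(total) - logden, -Inf)
    # update f: exp(-beta f_j) = sum_b P_b exp(logC[j,b]) (P unnormalized is
    # fine: a common factor shifts all f_j equally and cancels in P)
    A <- sweep(logC, 2L, logP, "+")      # J x B
    amax <- apply(A[, populated, drop = FALSE], 1L, max)
    lognum <- amax + log(rowSums(exp(sweep(A[, populated, drop = FALSE], 1L, amax))))
    fnew <- -lognum / beta
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < settings$tolerance) { converged <- TRUE; break }
  }
  W <- -logP / beta
  W[!populated] <- NA_real_
  W <- W - min(W, na.rm = TRUE)
  if (!converged)
    warning(sprintf("WHAM did not converge in %d iterations (last |df| = %.3g)",
                    settings$max_iter, delta))
  structure(list(xi = centers, W = W, counts = total,
                 temperature = temperature, converged = converged,
                 iterations = it, f = f, bin_width = bw),
            class = "pmf_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins (%.2f..%.2f A), T = %g K, %s after %d iterations\n",
              length(x$xi), min(x$xi), max(x$xi), x$temperature,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

.pmf_at <- function(profile, xi_query) {
  ok <- which(!is.na(profile$W))
  if (!length(ok)) stop("profile has no populated bins")
  d <- abs(profile$xi[ok] - xi_query)
  i <- ok[which.min(d)]
  if (min(d) > profile$bin_width)
    stop(sprintf("xi = %g is outside the populated range (nearest bin %.3g A away)",
                 xi_query, min(d)))
  profile$W[i]
}

#' Free-energy difference between two PMF profiles at a reaction coordinate
#'
#' Both profiles are anchored to 0 at their own minimum, so the difference
#' `W_a(xi) - W_b(xi)` compares barrier heights relative to the bound state,
#' not absolute offsets (adding a constant to a profile before anchoring
#' changes nothing).
#'
#' @param a,b [wham_solve()] results.
#' @param xi_query reaction coordinate (Angstrom); snapped to the nearest
#'   populated bin within one bin width.
#' @return difference in kcal/mol.
#' @export
pmf_barrier_difference <- function(a, b, xi_query) {
  stopifnot(inherits(a, "pmf_profile"), inherits(b, "pmf_profile"))
  .pmf_at(a, xi_query) - .pmf_at(b, xi_query)
}

#' Barrier height of a PMF between two coordinates
#'
#' Maximum of `W` over populated bins inside `[from, to]`, relative to the
#' profile minimum (which is 0 by anchoring).
#'
#' @param profile a `pmf_profile`.
#' @param from,to reaction-coordinate range (default full range).
#' @return barrier height in kcal/mol.
#' @export
pmf_barrier_height <- function(profile, from = -Inf, to = Inf) {
  sel <- !is.na(profile$W) & profile$xi >= from & profile$xi <= to
  if (!any(sel)) stop("no populated bins in the requested range")
  max(profile$W[sel])
}
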