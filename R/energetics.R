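# MM-PBSA-style binding free-energy aggregation from per-frame energy
# component tables, with cluster-based uncertainties and delta-delta-G
# ranking of peptide variants. Energy components are consumed, never
# computed: the Poisson-Boltzmann / surface-area terms come from an external
# engine or from the synthetic generator.

ENERGY_TERMS <- c("E_internal", "E_vdw", "E_elec", "G_polar", "G_nonpolar")
SYSTEMS <- c("complex", "receptor", "ligand")

#' Validate an energy frame table
#'
#' Per-frame energy components (kcal/mol) for the complex, the receptor and
#' the ligand, with an integer cluster label per frame. Every frame index
#' must be present for all three systems and cluster labels must agree across
#' the systems of a frame.
#'
#' @param df data frame with columns `system` (`complex`/`receptor`/`ligand`),
#'   `frame`, `cluster`, `E_internal`, `E_vdw`, `E_elec`, `G_polar`,
#'   `G_nonpolar`.
#' @return the validated data frame, classed `energy_frame_table`.
#' @export
energy_frame_table <- function(df) {
  need <- c("system", "frame", "cluster", ENERGY_TERMS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("energy table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$system %in% SYSTEMS))
    stop("system must be one of: ", paste(SYSTEMS, collapse = ", "))
  if (!all(is.finite(as.matrix(df[, ENERGY_TERMS]))))
    stop("non-finite energy components")
  frames <- sort(unique(df$frame))
  for (s in SYSTEMS) {
    have <- unique(df$frame[df$system == s])
    gap <- setdiff(frames, have)
    if (length(gap))
      stop(sprintf("incomplete table: system '%s' missing frame(s) %s",
                   s, paste(utils::head(gap, 5L), collapse = ",")))
  }
  cl <- df$cluster[df$system == "complex"][order(df$frame[df$system == "complex"])]
  if (any(cl < 1L)) stop("cluster labels must be positive integers")
  structure(df, class = c("energy_frame_table", "data.frame"))
}

#' Read / write energy frame tables (TSV)
#'
#' @param file path to a TSV with a one-line header (comment lines starting
#'   with `#` are ignored).
#' @return an [energy_frame_table()].
#' @export
read_energy_table <- function(file) {
  lines <- .as_lines(file)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  energy_frame_table(utils::read.table(text = body, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}

#' @rdname read_energy_table
#' @param table an [energy_frame_table()].
#' @export
write_energy_table <- function(table, file = NULL) {
  hdr <- .header_comment("energy frame table",
                         list(n_frames = length(unique(table$frame))))
  lines <- c(hdr, paste(names(table), collapse = "\t"),
             do.call(paste, c(unname(as.list(table)), sep = "\t")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' MM-PBSA binding free-energy aggregation
#'
#' For each system the frame free energy is
#' `G = E_internal + E_vdw + E_elec + G_polar + G_nonpolar`; the binding free
#' energy is the frame average `dG = <G_complex> - <G_receptor> - <G_ligand>`
#' (kcal/mol). No entropy term is ever added. The uncertainty is the sample
#' standard deviation (n-1 denominator) of the per-cluster mean `dG` values,
#' the clusters being the conformational clusters of the underlying
#' trajectory.
#'
#' @param table an [energy_frame_table()] (or data frame passing its checks).
#' @return object of class `binding_free_energy`: `dG` (kcal/mol),
#'   `term_means` (3 x 5 matrix, system by component), `cluster_means` (dG per
#'   cluster), `sd_over_clusters`, `n_frames`, `n_clusters`.
#' @export
mmpbsa_aggregate <- function(table) {
  table <- energy_frame_table(as.data.frame(table))
  G <- rowSums(as.matrix(table[, ENERGY_TERMS]))
  g_by <- function(s) {
    sub <- table$system == s
    v <- G[sub]; names(v) <- table$frame[sub]
    v[order(as.numeric(names(v)))]
  }
  gc <- g_by("complex"); gr <- g_by("receptor"); gl <- g_by("ligand")
  dg_frame <- gc - gr - gl
  sub <- table$system == "complex"
  cl <- table$cluster[sub][order(table$frame[sub])]
  if (length(unique(cl)) < 1L) stop("cluster partition is empty")
  cluster_means <- tapply(dg_frame, cl, mean)
  sdc <- if (length(cluster_means) > 1L) stats::sd(cluster_means) else 0
  term_means <- t(vapply(SYSTEMS, function(s)
    colMeans(as.matrix(table[table$system == s, ENERGY_TERMS, drop = FALSE])),
    numeric(length(ENERGY_TERMS))))
  structure(list(dG = mean(dg_frame), term_means = term_means,
                 cluster_means = as.numeric(cluster_means),
                 sd_over_clusters = sdc,
                 n_frames = length(dg_frame),
                 n_clusters = length(cluster_means)),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("dG_bind = %.3f kcal/mol (sd over %d clusters: %.3f; %d frames)\n",
              x$dG, x$n_clusters, x$sd_over_clusters, x$n_frames))
  invisible(x)
}

#' Rank peptide variants by binding free-energy change
#'
#' `ddG = dG_variant - dG_reference`: positive values mean weaker binding
#' than the reference peptide, so destabilizing C-terminal truncations rank
#' last.
#'
#' @param results named list of [mmpbsa_aggregate()] results (names are
#'   variant labels).
#' @param reference label of the reference variant (must be present).
#' @return data frame of class `ddg_table` with `variant`, `dG`, `sd`, `ddG`,
#'   sorted by `ddG` ascending; the reference row has `ddG = 0`.
#' @export
ddg_rank <- function(results, reference) {
  if (!reference %in% names(results))
    stop("unknown reference variant: ", reference)
  dg <- vapply(results, function(r) r$dG, numeric(1))
  sdv <- vapply(results, function(r) r$sd_over_clusters, numeric(1))
  out <- data.frame(variant = names(results), dG = unname(dg),
                    sd = unname(sdv),
                    ddG = unname(dg - dg[[reference]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ddG), ]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  class(out) <- c("ddg_table", "data.frame")
  out
}
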