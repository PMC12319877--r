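# Error metrics (global/local vector and magnitude errors) and the
# convergence-study driver comparing the real-time expansion against the
# direct FEM reference over random placements and mode counts.

#' Global vector and magnitude errors
#'
#' `GVE = ||E_est - E_ref|| / ||E_ref|| * 100` and
#' `GME = || |E_est| - |E_ref| || / ||E_ref|| * 100`, with `||.||` the
#' unweighted 2-norm over all stacked evaluation samples and `|.|` the
#' per-point magnitude.  An area-weighted variant is available via
#' `weights`.
#'
#' @param E_est,E_ref n x 3 field matrices at the same evaluation points.
#' @param weights optional per-point quadrature weights (e.g. facet
#'   areas); default unweighted.
#' @return list with `gve` and `gme`, in percent.
#' @export
global_errors <- function(E_est, E_ref, weights = NULL) {
  E_est <- as_matrix3(E_est, "E_est"); E_ref <- as_matrix3(E_ref, "E_ref")
  w <- if (is.null(weights)) rep(1, nrow(E_ref)) else weights
  nref2 <- sum(w * rowSums(E_ref^2))
  if (nref2 == 0) stop("reference field has zero norm")
  gve <- sqrt(sum(w * rowSums((E_est - E_ref)^2)) / nref2) * 100
  gme <- sqrt(sum(w * (row_norms(E_est) - row_norms(E_ref))^2) / nref2) * 100
  list(gve = gve, gme = gme)
}

#' Local (pointwise) errors normalized by the peak reference magnitude
#'
#' `LVE = |E_est - E_ref| / max|E_ref| * 100` and
#' `LME = ||E_est| - |E_ref|| / max|E_ref| * 100` per evaluation point.
#'
#' @inheritParams global_errors
#' @return matrix with columns `lve`, `lme` (percent per point).
#' @export
local_errors <- function(E_est, E_ref) {
  E_est <- as_matrix3(E_est, "E_est"); E_ref <- as_matrix3(E_ref, "E_ref")
  mref <- max(row_norms(E_ref))
  if (mref == 0) stop("reference field has zero norm")
  cbind(lve = row_norms(E_est - E_ref) / mref * 100,
        lme = abs(row_norms(E_est) - row_norms(E_ref)) / mref * 100)
}

#' Convergence study against the direct FEM reference
#'
#' For each placement, solves the reference FEM problem once and the
#' real-time expansion at every requested mode count, and records global
#' errors over all evaluation points and over the hotspot (points with
#' `|E_ref| >= hotspot_fraction * max|E_ref|`).
#'
#' @param session a `tms_realtime` session (built with
#'   `keep_basis = TRUE` if coefficient validation is also wanted).
#' @param mesh the session's [head_mesh()].
#' @param placements list of [placement()] objects (e.g. from
#'   [sample_scalp_placements()]).
#' @param mode_counts integer vector of expansion truncations.
#' @param hotspot_fraction threshold defining the hotspot subset
#'   (default 0.7).
#' @param op optional pre-assembled conduction operator (reused across
#'   placements).
#' @param verbose print progress.
#' @return data frame with one row per (placement, mode count):
#'   `placement`, `n_modes`, `gve`, `gme`, `gve_hot`, `gme_hot`;
#'   the per-mode-count mean/max summary in attribute `"summary"`.
#' @export
convergence_study <- function(session, mesh, placements, mode_counts,
                              hotspot_fraction = 0.7, op = NULL,
                              verbose = interactive()) {
  if (is.null(op)) op <- assemble_conduction_system(mesh)
  mode_counts <- sort(unique(as.integer(mode_counts)))
  if (max(mode_counts) > session$n_modes)
    stop("mode count exceeds the session basis")
  rows <- vector("list", length(placements) * length(mode_counts))
  ri <- 1L
  for (p in seq_along(placements)) {
    Eref <- tryCatch(
      reference_solve(session, mesh, placements[[p]], op = op),
      error = function(e) {
        message("reference solve failed for placement ", p, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(Eref)) next
    hot <- row_norms(Eref) >= hotspot_fraction * max(row_norms(Eref))
    a <- attr(realtime_solve(session, placements[[p]], n_use = 0L),
              "coefficients")
    for (nm in mode_counts) {
      Eest <- reconstruct_field(session, a, n_use = nm)
      ge <- global_errors(Eest, Eref)
      gh <- global_errors(Eest[hot, , drop = FALSE],
                          Eref[hot, , drop = FALSE])
      rows[[ri]] <- data.frame(placement = p, n_modes = nm,
                               gve = ge$gve, gme = ge$gme,
                               gve_hot = gh$gve, gme_hot = gh$gme)
      ri <- ri + 1L
    }
    if (verbose && p %% 10L == 0L)
      message("placement ", p, "/", length(placements))
  }
  out <- do.call(rbind, rows[seq_len(ri - 1L)])
  agg <- do.call(rbind, lapply(split(out, out$n_modes), function(d)
    data.frame(n_modes = d$n_modes[1],
               mean_gve = mean(d$gve), max_gve = max(d$gve),
               mean_gme = mean(d$gme), max_gme = max(d$gme),
               mean_gve_hot = mean(d$gve_hot),
               mean_gme_hot = mean(d$gme_hot))))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}

#' Export a convergence report
#'
#' Writes the per-placement rows and the per-mode-count summary of a
#' [convergence_study()] result as JSON (requires jsonlite) or CSV.
#'
#' @param study a [convergence_study()] result.
#' @param path output path; format chosen by extension (`.json`/`.csv`).
#' @export
write_convergence_report <- function(study, path) {
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite required for JSON reports")
    jsonlite::write_json(list(rows = study, summary = attr(study, "summary")),
                         path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(study, path, row.names = FALSE)
  }
  invisible(path)
}
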