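.halogens <- c("F", "Cl", "Br", "I")

#' Classify a site competition as regio- or chemoselective
#'
#' Competing electrophilic sites bearing the same halogen pose a
#' regioselectivity problem; different halogens a chemoselectivity problem.
#'
#' @param halogens Halogen element per candidate site (>= 2 sites, each in
#'   F/Cl/Br/I).
#' @return `"regio"` or `"chemo"`.
#' @export
classify_competition <- function(halogens) {
  if (length(halogens) < 2L) stop("need at least 2 sites")
  bad <- setdiff(unique(halogens), .halogens)
  if (length(bad))
    stop("non-halogen site element(s): ", paste(bad, collapse = ", "))
  if (length(unique(halogens)) == 1L) "regio" else "chemo"
}

#' Predict the major substitution site
#'
#' The predicted major product corresponds to the site with the lowest
#' predicted activation free energy. The margin is the gap to the
#' second-lowest barrier; an exact tie is flagged and broken
#' deterministically in favour of the earlier site label.
#'
#' @param sites data.frame with `site_label` and `dG_pred_kcal` (all
#'   finite), one row per candidate site.
#' @return List: `site` (predicted major label), `margin` (kcal/mol),
#'   `tie` (logical).
#' @export
predict_major <- function(sites) {
  if (nrow(sites) < 2L) stop("need at least 2 sites")
  dg <- sites$dG_pred_kcal
  if (any(!is.finite(dg))) {
    bad <- sites$site_label[!is.finite(dg)]
    stop("missing barrier for site(s): ", paste(bad, collapse = ", "))
  }
  o <- order(dg)               # stable: first label wins exact ties
  list(site = as.character(sites$site_label[o[1]]),
       margin = dg[o[2]] - dg[o[1]],
       tie = dg[o[2]] == dg[o[1]])
}

#' Top-1 selectivity accuracy, split by regio/chemo class
#'
#' Scores each substrate's competition with [predict_major()] against the
#' observed major site. Sites with missing predicted barriers are dropped
#' (with a message); competitions left with fewer than two sites are
#' excluded and logged.
#'
#' @param site_table data.frame with columns `substrate_id`, `site_label`,
#'   `halogen`, `dG_pred_kcal`, `observed_major_flag` (exactly one TRUE per
#'   substrate among surviving sites).
#' @return List of class `snar_selectivity`: `overall`, `regio`, `chemo`
#'   accuracies (`NA` with a flag when a class is empty), `counts`, and
#'   `details` (per-substrate data.frame).
#' @export
top1_accuracy <- function(site_table) {
  drop_na <- !is.finite(site_table$dG_pred_kcal)
  if (any(drop_na)) {
    message(sum(drop_na), " site(s) dropped for missing predicted barriers")
    site_table <- site_table[!drop_na, , drop = FALSE]
  }
  rows <- lapply(split(site_table, site_table$substrate_id), function(sub) {
    if (nrow(sub) < 2L) {
      message("substrate ", sub$substrate_id[1],
              " excluded: fewer than 2 scored sites")
      return(NULL)
    }
    if (sum(sub$observed_major_flag) != 1L) {
      message("substrate ", sub$substrate_id[1],
              " excluded: observed major site not among scored sites")
      return(NULL)
    }
    pm <- predict_major(sub)
    data.frame(substrate_id = sub$substrate_id[1],
               class = classify_competition(sub$halogen),
               predicted = pm$site, margin = pm$margin, tie = pm$tie,
               observed = as.character(
                 sub$site_label[sub$observed_major_flag][1]),
               correct = pm$site ==
                 as.character(sub$site_label[sub$observed_major_flag][1]))
  })
  details <- do.call(rbind, rows)
  if (is.null(details)) stop("no scorable competitions")
  acc <- function(cls) {
    sel <- if (is.null(cls)) rep(TRUE, nrow(details)) else
      details$class == cls
    if (!any(sel)) return(NA_real_)
    mean(details$correct[sel])
  }
  structure(list(overall = acc(NULL), regio = acc("regio"),
                 chemo = acc("chemo"),
                 counts = c(total = nrow(details),
                            regio = sum(details$class == "regio"),
                            chemo = sum(details$class == "chemo")),
                 details = details),
            class = "snar_selectivity")
}

#' @export
print.snar_selectivity <- function(x, ...) {
  cat(sprintf(
    "Top-1 selectivity: %.0f%% overall (n=%d), %.0f%% regio (n=%d), %.0f%% chemo (n=%d)\n",
    100 * x$overall, x$counts["total"],
    100 * x$regio, x$counts["regio"],
    100 * x$chemo, x$counts["chemo"]))
  invisible(x)
}

#' Default reaction conditions for selectivity prediction
#'
#' When patent-derived competitions lack conditions, neutral reactions are
#' assigned acetonitrile and ionic reactions methanol, both at 25 C.
#'
#' @param charge_state `"neutral"` or `"ionic"`.
#' @return List: `solvent`, `temperature_K` (298.15).
#' @export
default_conditions <- function(charge_state = c("neutral", "ionic")) {
  charge_state <- match.arg(charge_state)
  list(solvent = if (charge_state == "neutral") "acetonitrile" else
    "methanol", temperature_K = 298.15)
}
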