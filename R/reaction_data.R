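#' Read and validate a reaction table
#'
#' The reaction table has one row per kinetic measurement with columns
#' `rxn_id`, `reaction_smiles`, `nucleophile_class`, `leaving_class`,
#' `electrophile_id`, `nucleophile_id`, `solvent`, `temperature_K`, `k_obs`
#' (s^-1, pseudo-first-order; may be empty) and `dG_exp_kcal` (kcal/mol; may
#' be empty). At least one of `k_obs`/`dG_exp_kcal` must be present per row;
#' a missing barrier is filled in from the rate constant via the Eyring
#' equation at the row's temperature. When both are present they must agree
#' to 0.01 kcal/mol.
#'
#' @param path CSV file path, or a data.frame already in the schema above.
#' @return A validated data.frame with a resolved `dG_exp_kcal` column.
#' @export
read_reactions <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  req <- c("rxn_id", "reaction_smiles", "nucleophile_class", "leaving_class",
           "electrophile_id", "nucleophile_id", "solvent", "temperature_K",
           "k_obs", "dG_exp_kcal")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("reaction table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("reaction table is empty")
  if (anyDuplicated(df$rxn_id))
    stop("duplicated rxn_id: ",
         paste(unique(df$rxn_id[duplicated(df$rxn_id)]), collapse = ", "))
  df$temperature_K <- as.numeric(df$temperature_K)
  df$k_obs <- suppressWarnings(as.numeric(df$k_obs))
  df$dG_exp_kcal <- suppressWarnings(as.numeric(df$dG_exp_kcal))
  if (any(!is.finite(df$temperature_K) | df$temperature_K <= 0))
    stop("temperature_K must be > 0 for every row")
  bad_k <- !is.na(df$k_obs) & df$k_obs <= 0
  if (any(bad_k))
    stop("k_obs must be > 0 (rows: ",
         paste(df$rxn_id[bad_k], collapse = ", "), ")")
  none <- is.na(df$k_obs) & is.na(df$dG_exp_kcal)
  if (any(none))
    stop("rows with neither k_obs nor dG_exp_kcal: ",
         paste(df$rxn_id[none], collapse = ", "))
  both <- !is.na(df$k_obs) & !is.na(df$dG_exp_kcal)
  if (any(both)) {
    implied <- eyring_barrier(df$k_obs[both], df$temperature_K[both])
    off <- abs(implied - df$dG_exp_kcal[both]) > 0.01
    if (any(off))
      stop("k_obs and dG_exp_kcal violate the Eyring relation by > 0.01 ",
           "kcal/mol (rows: ",
           paste(df$rxn_id[both][off], collapse = ", "), ")")
  }
  fill <- is.na(df$dG_exp_kcal)
  if (any(fill))
    df$dG_exp_kcal[fill] <- eyring_barrier(df$k_obs[fill],
                                           df$temperature_K[fill])
  df
}

#' Read a solvent-property table
#'
#' Maps solvent names to the first five principal components of a curated
#' solvent-property database (columns `solvent`, `PC1`..`PC5`).
#'
#' @param path CSV path or data.frame.
#' @return data.frame keyed by `solvent`.
#' @export
read_solvents <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  req <- c("solvent", paste0("PC", 1:5))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("solvent table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$solvent)) stop("duplicated solvent names")
  df
}

#' Summarize a kinetic dataset
#'
#' Computes the counts and barrier statistics used to characterise a
#' reaction dataset: total measurements, unique reactions (unique
#' `reaction_smiles`), how many unique reactions were run under one versus
#' several conditions, barrier range and mean, and descending frequency
#' tables over nucleophile classes, leaving classes and their combinations.
#'
#' @param reactions Validated reaction table (see [read_reactions()]).
#' @param solvents Optional solvent table; unresolvable solvent names are
#'   reported as warnings, never as failures.
#' @return An object of class `snar_summary`.
#' @export
summarize_reactions <- function(reactions, solvents = NULL) {
  if (nrow(reactions) == 0L) stop("empty dataset")
  if (any(is.na(reactions$dG_exp_kcal)))
    stop("dG_exp_kcal must be resolvable for every record")
  if (!is.null(solvents)) {
    unknown <- setdiff(unique(reactions$solvent), solvents$solvent)
    if (length(unknown))
      warning("solvents not in solvent table: ",
              paste(unknown, collapse = ", "))
  }
  per_rxn <- table(reactions$reaction_smiles)
  dG <- reactions$dG_exp_kcal
  srt <- function(x) sort(table(x), decreasing = TRUE)
  out <- list(
    n_total = nrow(reactions),
    n_unique_reactions = length(per_rxn),
    n_single_condition = sum(per_rxn == 1L),
    n_multi_condition = sum(per_rxn > 1L),
    dG_min = min(dG), dG_max = max(dG), dG_mean = mean(dG),
    class_counts = list(
      nucleophile = srt(reactions$nucleophile_class),
      leaving = srt(reactions$leaving_class),
      combination = srt(paste(reactions$nucleophile_class,
                              reactions$leaving_class, sep = "/"))
    )
  )
  class(out) <- "snar_summary"
  out
}

#' @export
print.snar_summary <- function(x, ...) {
  cat(sprintf(
    "SNAr kinetic dataset: %d measurements, %d unique reactions\n",
    x$n_total, x$n_unique_reactions))
  cat(sprintf("  single-condition: %d, multi-condition: %d\n",
              x$n_single_condition, x$n_multi_condition))
  cat(sprintf("  dG_exp range %.1f-%.1f kcal/mol, mean %.1f\n",
              x$dG_min, x$dG_max, x$dG_mean))
  invisible(x)
}

#' Draw a reproducible train/test split
#'
#' Splits measurement rows into train and test. With `grouping = "none"` the
#' split is at the row level with `|train| = floor(fraction_train * n)`.
#' Under grouping (`"reaction"`, `"electrophile"`, `"nucleophile"`) whole
#' groups are assigned so that no group straddles the split; groups are
#' accumulated in shuffled order until the training fraction is reached.
#'
#' @param reactions Reaction table.
#' @param fraction_train Training fraction in (0, 1). Default 0.8.
#' @param seed Integer seed; the plan is a pure function of
#'   (dataset, fraction, seed, grouping).
#' @param grouping One of `"none"`, `"reaction"`, `"electrophile"`,
#'   `"nucleophile"`.
#' @return List of class `snar_split`: `train_ids`, `test_ids`, `seed`,
#'   `fraction_train`, `grouping`.
#' @export
make_split <- function(reactions, fraction_train = 0.8, seed = 1L,
                       grouping = c("none", "reaction", "electrophile",
                                    "nucleophile")) {
  grouping <- match.arg(grouping)
  if (nrow(reactions) == 0L) stop("empty dataset")
  if (!is.numeric(fraction_train) || fraction_train <= 0 ||
      fraction_train >= 1)
    stop("fraction_train must be in (0, 1)")
  ids <- as.character(reactions$rxn_id)
  key <- switch(grouping,
    none = ids,
    reaction = as.character(reactions$reaction_smiles),
    electrophile = as.character(reactions$electrophile_id),
    nucleophile = as.character(reactions$nucleophile_id))
  if (any(is.na(key) | key == ""))
    stop("grouping key missing for some rows")
  n <- length(ids)
  train_ids <- with_seed(seed, {
    if (grouping == "none") {
      sort(sample(ids, floor(fraction_train * n)))
    } else {
      groups <- unique(key)
      ord <- sample(groups)
      sizes <- as.integer(table(key)[ord])
      take <- cumsum(sizes) <= floor(fraction_train * n)
      if (!any(take)) take[1] <- TRUE   # never an empty training set
      sort(ids[key %in% ord[take]])
    }
  })
  out <- list(train_ids = train_ids, test_ids = sort(setdiff(ids, train_ids)),
              seed = as.integer(seed), fraction_train = fraction_train,
              grouping = grouping)
  class(out) <- "snar_split"
  out
}
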