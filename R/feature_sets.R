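# cache of the packaged feature-set manifest
.manifest_env <- new.env(parent = emptyenv())

feature_manifest <- function() {
  if (is.null(.manifest_env$m)) {
    path <- system.file("extdata", "feature_sets.json", package = "snarml")
    if (path == "") path <- file.path("inst", "extdata", "feature_sets.json")
    .manifest_env$m <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .manifest_env$m
}

#' Column membership of a named descriptor feature set
#'
#' The package ships a manifest defining the named feature sets over the
#' descriptor table: `X_full` (all 34 descriptors), `X_noTS` (25 ground-state
#' descriptors, no transition-state information), `X_small` (12
#' expert-chosen descriptors whose only TS member is the DFT barrier
#' `dG_dft`), `X_trad` (`X_noTS` without the surface-electron descriptors
#' Vs, Is_min, Es_min, P_int) and `X_surf` (`X_noTS` without the traditional
#' electronic descriptors). Reaction temperature is deliberately absent from
#' every set: in real kinetic datasets it correlates with the target because
#' slow reactions are run hot.
#'
#' @param name Feature-set name.
#' @return Character vector of descriptor-table column names.
#' @export
feature_set_columns <- function(name = c("X_full", "X_noTS", "X_small",
                                         "X_trad", "X_surf")) {
  name <- match.arg(name)
  feature_manifest()$sets[[name]]
}

#' Describe a feature set for model building
#'
#' @param name Named set (see [feature_set_columns()]) or `"custom"`.
#' @param columns For `name = "custom"`, the ordered descriptor columns.
#' @param pf2 Apply second-order polynomial/interaction expansion
#'   ([pf2_expand()]) after assembly.
#' @param include_fingerprint Append a Morgan reaction difference
#'   fingerprint block.
#' @param fp_radius,fp_width Fingerprint radius (default 3 bonds) and folded
#'   width (default 2048, count folding).
#' @param standardize Z-score columns using training-partition statistics
#'   (applied inside model fitting, not at assembly).
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(name = "X_full", columns = NULL, pf2 = FALSE,
                             include_fingerprint = FALSE, fp_radius = 3L,
                             fp_width = 2048L, standardize = TRUE) {
  if (name == "custom") {
    if (is.null(columns)) stop("custom spec requires columns")
  } else {
    columns <- feature_set_columns(name)
  }
  structure(list(name = name, columns = columns, pf2 = pf2,
                 include_fingerprint = include_fingerprint,
                 fp_radius = as.integer(fp_radius),
                 fp_width = as.integer(fp_width),
                 standardize = standardize),
            class = "feature_set_spec")
}

#' Assemble a feature matrix and target vector
#'
#' Joins the reaction table to the descriptor table on `rxn_id`, selects the
#' spec's columns in order, optionally applies PF2 expansion and appends a
#' Morgan difference fingerprint block (with the five solvent principal
#' components concatenated when a solvent table is given). Row order follows
#' the reaction table.
#'
#' @param reactions Reaction table (validated).
#' @param descriptors Descriptor table keyed by `rxn_id`.
#' @param spec A [feature_set_spec()].
#' @param solvents Optional solvent table for the fingerprint solvent block.
#' @return List with `X` (numeric matrix, rownames = rxn_id), `y`
#'   (experimental barriers, kcal/mol) and `manifest` (column names).
#' @export
assemble_features <- function(reactions, descriptors, spec = feature_set_spec(),
                              solvents = NULL) {
  stopifnot(inherits(spec, "feature_set_spec"))
  unmatched <- setdiff(reactions$rxn_id, descriptors$rxn_id)
  if (length(unmatched))
    stop("rxn_ids missing from descriptor table: ",
         paste(unmatched, collapse = ", "))
  idx <- match(reactions$rxn_id, descriptors$rxn_id)
  desc <- descriptors[idx, , drop = FALSE]
  if (length(spec$columns)) {
    missing_cols <- setdiff(spec$columns, names(desc))
    if (length(missing_cols))
      stop("descriptor table missing columns: ",
           paste(missing_cols, collapse = ", "))
    X <- as.matrix(desc[, spec$columns, drop = FALSE])
    storage.mode(X) <- "double"
    if (any(!is.finite(X)))
      stop("non-finite descriptor values after assembly")
    if (spec$pf2) X <- pf2_expand(X)
  } else {
    X <- matrix(numeric(0), nrow = nrow(reactions), ncol = 0)
  }
  if (spec$include_fingerprint) {
    fps <- t(vapply(reactions$reaction_smiles, function(s)
      morgan_difference_fingerprint(s, radius = spec$fp_radius,
                                    width = spec$fp_width),
      numeric(spec$fp_width)))
    colnames(fps) <- paste0("fp", seq_len(spec$fp_width) - 1L)
    if (!is.null(solvents))
      fps <- attach_solvent_pcs(fps, solvents, reactions)
    X <- cbind(X, fps)
  }
  rownames(X) <- reactions$rxn_id
  list(X = X, y = reactions$dG_exp_kcal, manifest = colnames(X))
}

#' Second-order polynomial and interaction expansion (PF2)
#'
#' Appends, after the original d columns, all squares and pairwise products
#' x_i * x_j for i <= j in lexicographic (i, j) order, giving
#' d + d(d+1)/2 columns. No bias column is added.
#'
#' @param X Numeric matrix with d >= 1 columns.
#' @return Expanded matrix; new columns named `colA.x.colB`.
#' @export
pf2_expand <- function(X) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d < 1L) stop("pf2_expand needs at least one column")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  ext <- X[, pairs[, "row"], drop = FALSE] * X[, pairs[, "col"], drop = FALSE]
  colnames(ext) <- paste0(colnames(X)[pairs[, "row"]], ".x.",
                          colnames(X)[pairs[, "col"]])
  cbind(X, ext)
}

#' Append solvent principal components to a feature block
#'
#' Concatenates the five solvent principal components PC1..PC5, resolved per
#' reaction from the solvent table, to the right of `X`.
#'
#' @param X Numeric matrix, rows aligned with `reactions`.
#' @param solvents Solvent table (see [read_solvents()]).
#' @param reactions Reaction table supplying the `solvent` column.
#' @return Matrix with five extra columns `PC1`..`PC5`.
#' @export
attach_solvent_pcs <- function(X, solvents, reactions) {
  unknown <- setdiff(unique(reactions$solvent), solvents$solvent)
  if (length(unknown))
    stop("unknown solvent(s): ", paste(unknown, collapse = ", "))
  idx <- match(reactions$solvent, solvents$solvent)
  pcs <- as.matrix(solvents[idx, paste0("PC", 1:5), drop = FALSE])
  rownames(pcs) <- NULL
  cbind(X, pcs)
}
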