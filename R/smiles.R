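# Minimal SMILES reader covering the subset needed for SNAr reaction
# fingerprints: organic-subset atoms, aromatic lowercase atoms, bracket
# atoms with charge/explicit H, branches, ring closures (incl. %nn), dots,
# and bond symbols - = # :. Stereo markers and isotopes are ignored.

.organic <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
              F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset plus bracket atoms with charges and explicit
#' hydrogen counts, aromatic lowercase atoms, branches, ring-bond closures
#' and disconnected components ('.'). Implicit hydrogens are assigned from
#' standard valences adjusted by formal charge; aromatic bonds count 1.5
#' towards the valence sum. Stereochemistry and isotopes are discarded.
#'
#' @param smiles A single SMILES string.
#' @return List with `atoms` (data.frame: `elem`, `aromatic`, `charge`,
#'   `hcount`, `degree`) and `bonds` (data.frame: `a1`, `a2`, `order`;
#'   aromatic order 1.5).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("smiles must be a single string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elem <- character(); arom <- logical(); charge <- integer()
  hexp <- integer()   # explicit H from brackets, NA_integer_ otherwise
  b1 <- integer(); b2 <- integer(); bord <- numeric()
  stack <- integer(); prev <- NA_integer_
  pending <- NA_real_           # explicit bond symbol awaiting next atom
  ring <- list()                # open ring closures: label -> c(atom, order)
  bond_sym <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5)

  add_atom <- function(el, ar, ch, hh) {
    elem[length(elem) + 1L] <<- el
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    hexp[length(hexp) + 1L] <<- hh
    length(elem)
  }
  add_bond <- function(a, b, ord) {
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- ord
  }
  connect <- function(idx) {
    force(idx)   # add_atom side effects must land before arom is read
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom[prev] && arom[idx]) 1.5 else 1
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pending <<- NA_real_
  }
  close_ring <- function(lab) {
    if (is.null(ring[[lab]])) {
      ring[[lab]] <<- c(prev, pending)
      pending <<- NA_real_
    } else {
      open <- ring[[lab]]; ring[[lab]] <<- NULL
      ord <- pending
      if (is.na(ord)) ord <- open[2]
      if (is.na(ord)) ord <- if (arom[open[1]] && arom[prev]) 1.5 else 1
      add_bond(open[1], prev, ord)
      pending <<- NA_real_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    }
    else if (ch %in% names(bond_sym)) { pending <- bond_sym[[ch]]; i <- i + 1L }
    else if (ch == "/" || ch == "\\") { pending <- 1; i <- i + 1L }
    else if (ch == ".") { prev <- NA_integer_; pending <- NA_real_; i <- i + 1L }
    else if (grepl("[0-9]", ch)) { close_ring(ch); i <- i + 1L }
    else if (ch == "%") {
      if (i + 2L > n) stop("bad ring label in SMILES: ", smiles)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    }
    else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in SMILES: ", smiles)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- gsub("^[0-9]+", "", body)      # isotope
      body <- gsub("@+H?", "@", body); body <- gsub("@", "", body)
      m <- regmatches(body, regexec(
        "^([A-Z][a-z]?|as|se|[bcnops])(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "] in ", smiles)
      el <- m[2]
      ar <- el %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      if (ar) el <- paste0(toupper(substr(el, 1, 1)), substring(el, 2))
      hh <- if (m[3] == "") 0L else if (m[3] == "H") 1L else
        as.integer(substring(m[3], 2))
      chg <- 0L
      if (m[4] != "") {
        if (grepl("^[+-]+$", m[4]))
          chg <- nchar(m[4]) * (if (substr(m[4], 1, 1) == "+") 1L else -1L)
        else {
          mag <- if (nchar(m[4]) == 1L) 1L else as.integer(substring(m[4], 2))
          chg <- mag * (if (substr(m[4], 1, 1) == "+") 1L else -1L)
        }
      }
      connect(add_atom(el, ar, chg, hh))
      i <- j + 1L
    }
    else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        connect(add_atom(two, FALSE, 0L, NA_integer_)); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        connect(add_atom(ch, FALSE, 0L, NA_integer_)); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        connect(add_atom(toupper(ch), TRUE, 0L, NA_integer_)); i <- i + 1L
      } else {
        stop("unsupported SMILES character '", ch, "' in ", smiles)
      }
    }
  }
  if (length(ring)) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(stack)) stop("unbalanced '(' in SMILES: ", smiles)
  natom <- length(elem)
  if (natom == 0L) stop("empty SMILES")
  bondsum <- numeric(natom); degree <- integer(natom)
  for (k in seq_along(b1)) {
    bondsum[b1[k]] <- bondsum[b1[k]] + bord[k]
    bondsum[b2[k]] <- bondsum[b2[k]] + bord[k]
    degree[b1[k]] <- degree[b1[k]] + 1L
    degree[b2[k]] <- degree[b2[k]] + 1L
  }
  hcount <- hexp
  for (a in seq_len(natom)) {
    if (is.na(hcount[a])) {
      val <- .organic[[elem[a]]] + charge[a]
      hcount[a] <- max(0L, as.integer(round(val - bondsum[a])))
    }
  }
  list(atoms = data.frame(elem = elem, aromatic = arom, charge = charge,
                          hcount = hcount, degree = degree,
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = b1, a2 = b2, order = bord))
}

# deterministic 31-bit string hash (polynomial, base 131)
.str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

#' Circular (Morgan-style) atom environment identifiers
#'
#' Computes hashed identifiers of the circular substructure environments of
#' every atom at radii 0..`radius`, by iterated neighbourhood hashing of
#' atom invariants (element, charge, aromaticity, degree, hydrogen count)
#' with bond orders. Environments generated at radius r are a subset of
#' those generated at radius r + 1 by construction.
#'
#' @param mol Parsed molecule from [parse_smiles()].
#' @param radius Maximum environment radius in bonds.
#' @return Numeric vector of environment identifiers (one per atom and
#'   radius, multiset).
#' @export
morgan_environments <- function(mol, radius = 3L) {
  atoms <- mol$atoms; bonds <- mol$bonds
  natom <- nrow(atoms)
  nb <- vector("list", natom)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      nb[[bonds$a1[k]]] <- rbind(nb[[bonds$a1[k]]],
                                 c(bonds$a2[k], bonds$order[k]))
      nb[[bonds$a2[k]]] <- rbind(nb[[bonds$a2[k]]],
                                 c(bonds$a1[k], bonds$order[k]))
    }
  }
  inv <- vapply(seq_len(natom), function(a) .str_hash(
    paste(atoms$elem[a], atoms$charge[a], atoms$aromatic[a],
          atoms$degree[a], atoms$hcount[a], sep = "|")), numeric(1))
  envs <- inv
  r <- 0L
  while (r < radius) {
    newinv <- vapply(seq_len(natom), function(a) {
      if (is.null(nb[[a]])) return(.str_hash(paste0("t", inv[a])))
      parts <- sort(paste0(nb[[a]][, 2], ":", inv[nb[[a]][, 1]]))
      .str_hash(paste0(inv[a], "|", paste(parts, collapse = ",")))
    }, numeric(1))
    inv <- newinv
    envs <- c(envs, inv)
    r <- r + 1L
  }
  envs
}

#' Morgan reaction difference fingerprint
#'
#' Folded count vector of the circular environments of the product side
#' minus those of the reactant side of a reaction SMILES
#' (`reactants>agents>products`); agents are ignored. Count (not binary)
#' folding is used so that swapping reactants and products exactly negates
#' the vector. A radius of 3 bonds captures substituent effects from the
#' position para to the reacting ring carbon.
#'
#' @param reaction_smiles Reaction SMILES with at least a reactant and a
#'   product part.
#' @param radius Environment radius in bonds (default 3).
#' @param width Folded vector width (default 2048).
#' @return Numeric vector of length `width` (signed counts).
#' @export
morgan_difference_fingerprint <- function(reaction_smiles, radius = 3L,
                                          width = 2048L) {
  parts <- strsplit(reaction_smiles, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L || parts[1] == "" || parts[3] == "")
    stop("not a valid reaction SMILES (need reactants>agents>products): ",
         reaction_smiles)
  fold <- function(smi) {
    envs <- morgan_environments(parse_smiles(smi), radius = radius)
    tabulate((envs %% width) + 1L, nbins = width)
  }
  fold(parts[3]) - fold(parts[1])
}
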