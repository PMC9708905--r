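#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic-subset atoms (B, C, N, O, P, S, F, Cl, Br, I),
#' aromatic lowercase atoms (b, c, n, o, p, s), bracket atoms with an
#' explicit element, charge and hydrogen count, ring-closure digits
#' (including `%nn`), branches, explicit bond orders (`-`, `=`, `#`, `:`)
#' and dot-separated fragments. Stereochemistry (`@`, `/`, `\`) and isotopes
#' are rejected; aromaticity is taken exactly as written (no perception).
#' The default bond between two aromatic atoms is aromatic, otherwise single.
#'
#' @param text A single SMILES string.
#' @return An object of class `mol_graph`: list with `atoms` (data.frame
#'   `element`, `aromatic`, `charge`, `in_ring`) and `bonds` (data.frame
#'   `i`, `j`, `order` with order one of `-`, `=`, `#`, `:`).
#' @examples
#' parse_smiles("c1ccccc1")  # benzene
#' @export
parse_smiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  perr <- function(pos, msg) stop("SMILES parse error at position ", pos,
                                  ": ", msg, call. = FALSE)
  elements <- character(0); aromatic <- logical(0); charge <- integer(0)
  bi <- integer(0); bj <- integer(0); border <- character(0)
  prev <- NA_integer_          # previous atom index
  pending <- NA_character_     # explicit bond order awaiting next atom
  branch <- integer(0)         # stack of atom indices
  rings <- list()              # closure number -> list(atom, order, pos)
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")

  add_atom <- function(el, arom, chg, pos) {
    elements[length(elements) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    idx <- length(elements)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic[prev] && arom) ":" else "-"
      if (ord == ":" && !(aromatic[prev] && arom))
        perr(pos, "aromatic bond between non-aromatic atoms")
      bi[length(bi) + 1L] <<- prev
      bj[length(bj) + 1L] <<- idx
      border[length(border) + 1L] <<- ord
    }
    pending <<- NA_character_
    prev <<- idx
    idx
  }

  close_ring <- function(num, pos) {
    if (is.na(prev)) perr(pos, "ring closure before any atom")
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending, pos = pos)
      pending <<- NA_character_
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      ord <- pending
      if (is.na(ord)) ord <- open$order
      if (!is.na(open$order) && !is.na(pending) && open$order != pending)
        perr(pos, "conflicting ring bond orders")
      if (is.na(ord)) ord <- if (aromatic[open$atom] && aromatic[prev]) ":" else "-"
      if (open$atom == prev) perr(pos, "ring bond to self")
      bi[length(bi) + 1L] <<- open$atom
      bj[length(bj) + 1L] <<- prev
      border[length(border) + 1L] <<- ord
      pending <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% organic2) {
      add_atom(two, FALSE, 0L, i); i <- i + 2L
    } else if (ch %in% organic1) {
      add_atom(ch, FALSE, 0L, i); i <- i + 1L
    } else if (ch %in% aromatic1) {
      add_atom(toupper(ch), TRUE, 0L, i); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      if (j <= n && chars[j] %in% as.character(0:9))
        perr(j, "isotopes not supported")
      el <- ""; arom <- FALSE
      if (j <= n && grepl("^[A-Z]$", chars[j])) {
        el <- chars[j]; j <- j + 1L
        if (j <= n && grepl("^[a-z]$", chars[j]) && chars[j] != "h" &&
            paste0(el, chars[j]) %in% c(organic2, "Si", "Se", "As", "Na", "Li",
                                        "Mg", "Ca", "Fe", "Zn", "Cu", "Mn")) {
          el <- paste0(el, chars[j]); j <- j + 1L
        }
      } else if (j <= n && chars[j] %in% aromatic1) {
        el <- toupper(chars[j]); arom <- TRUE; j <- j + 1L
      } else perr(j, "unknown element in bracket atom")
      if (j <= n && chars[j] == "@") perr(j, "stereochemistry not supported")
      hcount <- 0L
      if (j <= n && chars[j] == "H") {
        j <- j + 1L; hcount <- 1L
        if (j <= n && grepl("^[0-9]$", chars[j])) {
          hcount <- as.integer(chars[j]); j <- j + 1L
        }
      }
      chg <- 0L
      if (j <= n && chars[j] %in% c("+", "-")) {
        s <- if (chars[j] == "+") 1L else -1L
        j <- j + 1L; chg <- s
        while (j <= n && chars[j] == ifelse(s > 0, "+", "-")) {
          chg <- chg + s; j <- j + 1L
        }
        if (j <= n && grepl("^[0-9]$", chars[j])) {
          chg <- s * as.integer(chars[j]); j <- j + 1L
        }
      }
      if (j > n || chars[j] != "]") perr(j, "expected ]")
      add_atom(el, arom, chg, i)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (!is.na(pending)) perr(i, "two consecutive bond symbols")
      pending <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      perr(i, "stereo bonds not supported")
    } else if (ch == "(") {
      if (is.na(prev)) perr(i, "branch before any atom")
      branch <- c(branch, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(branch) == 0L) perr(i, "unbalanced parentheses")
      prev <- branch[length(branch)]
      branch <- branch[-length(branch)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        perr(i, "%% must be followed by two digits")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else {
      perr(i, paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(branch) > 0L) perr(n, "unbalanced parentheses")
  if (length(rings) > 0L)
    perr(rings[[1]]$pos, paste0("unclosed ring bond ", names(rings)[1]))
  if (length(elements) == 0L) perr(1, "no atoms")
  atoms <- data.frame(element = elements, aromatic = aromatic,
                      charge = charge, stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border,
                      stringsAsFactors = FALSE)
  atoms$in_ring <- ring_membership(nrow(atoms), bonds)
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

# an atom is in a ring iff it touches a non-bridge edge
ring_membership <- function(n_atoms, bonds) {
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds) == 0L) return(in_ring)
  connected <- function(a, b, skip) {
    seen <- rep(FALSE, n_atoms); seen[a] <- TRUE; queue <- a
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in seq_len(nrow(bonds))) {
        if (e == skip) next
        w <- if (bonds$i[e] == v) bonds$j[e] else if (bonds$j[e] == v) bonds$i[e] else next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[b]
  }
  for (e in seq_len(nrow(bonds))) {
    if (connected(bonds$i[e], bonds$j[e], e)) {
      in_ring[bonds$i[e]] <- TRUE; in_ring[bonds$j[e]] <- TRUE
    }
  }
  in_ring
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      sum(x$atoms$aromatic), "aromatic\n")
  invisible(x)
}

# fragment symbol for an atom: lowercase if aromatic, charge suffix appended
atom_symbols <- function(mol) {
  sym <- ifelse(mol$atoms$aromatic, tolower(mol$atoms$element),
                mol$atoms$element)
  chg <- mol$atoms$charge
  suff <- ifelse(chg == 0, "",
                 paste0(ifelse(chg > 0, "+", "-"),
                        ifelse(abs(chg) > 1, abs(chg), "")))
  paste0(sym, suff)
}
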