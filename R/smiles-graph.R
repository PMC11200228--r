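# Internal molecular-graph engine for SMILES.
#
# OpenBabel (via ChemmineOB) supplies canonical SMILES and global descriptors,
# but it is deliberately lenient with malformed input and offers no access to
# atom ordering. Everything that needs the graph itself -- strict validation,
# randomized (augmented) SMILES writing, Bemis-Murcko scaffolds, ring counts,
# Morgan fingerprints, molecular weight -- runs on this parser instead.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# smallest-first allowed valences used for implicit-H assignment and the
# strict valence check on organic-subset atoms
.DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904
)

.ATOMIC_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Se = 34L, Br = 35L, I = 53L
)

smi_fail <- function(msg) structure(list(ok = FALSE, error = msg), class = "smigraph")

# Implicit hydrogen count the SMILES reader assigns to a bare (non-bracket)
# atom. Aromatic C/B carry one delocalized double bond beyond their sigma
# framework; bare aromatic N/P (pyridine-type) and O/S contribute a lone pair
# and never carry implicit H. Returns NA when the valence is overfilled for a
# non-aromatic atom.
.implied_bare_h <- function(sym, arom, bond, ks) {
  bs <- 0L
  for (k in ks) bs <- bs + if (bond$aromatic[k]) 1L else bond$order[k]
  if (arom) {
    if (!(sym %in% c("C", "B"))) return(0L)
    dv <- .DEFAULT_VALENCE[[sym]][1L]
    return(max(0L, dv - bs - 1L))
  }
  if (!(sym %in% names(.DEFAULT_VALENCE))) return(0L)
  dv <- .DEFAULT_VALENCE[[sym]]
  dv <- dv[dv >= bs]
  if (length(dv) == 0L) return(NA_integer_)
  dv[1L] - bs
}

#' @keywords internal
#' @noRd
smi_parse <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(smi_fail("empty or non-character SMILES"))
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  symbol <- character(0); aromatic <- logical(0); charge <- integer(0)
  isotope <- integer(0); hspec <- integer(0)  # NA = implicit
  chiral <- character(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_ord <- integer(0)
  b_arom <- logical(0); b_stereo <- character(0)

  add_atom <- function(sym, arom, chg = 0L, iso = NA_integer_,
                       h = NA_integer_, chi = "") {
    symbol[length(symbol) + 1L] <<- sym
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    isotope[length(isotope) + 1L] <<- iso
    hspec[length(hspec) + 1L] <<- h
    chiral[length(chiral) + 1L] <<- chi
    length(symbol)
  }
  add_bond <- function(a1, a2, ord, arom, stereo = "") {
    if (a1 == a2) stop("ring bond to self")
    k <- length(b_a1) + 1L
    b_a1[k] <<- a1; b_a2[k] <<- a2; b_ord[k] <<- ord
    b_arom[k] <<- arom; b_stereo[k] <<- stereo
  }

  prev <- 0L                 # previous atom index (0 = none)
  stack <- integer(0)        # branch stack
  branch_mark <- integer(0)  # atom count at each '(' (empty-branch check)
  pending <- ""              # pending bond symbol
  rings <- list()            # closure digit -> list(atom, bondsym)
  i <- 1L

  parse_error <- NULL
  bond_between <- function(a1, a2, sym) {
    # resolve an explicit/implicit bond symbol between two parsed atoms
    if (sym == "") {
      if (aromatic[a1] && aromatic[a2]) add_bond(a1, a2, 1L, TRUE)
      else add_bond(a1, a2, 1L, FALSE)
    } else if (sym == "-") add_bond(a1, a2, 1L, FALSE)
    else if (sym == "=") add_bond(a1, a2, 2L, FALSE)
    else if (sym == "#") add_bond(a1, a2, 3L, FALSE)
    else if (sym == ":") add_bond(a1, a2, 1L, TRUE)
    else if (sym == "/" || sym == "\\") add_bond(a1, a2, 1L, FALSE, sym)
    else stop("unsupported bond symbol '", sym, "'")
  }

  res <- tryCatch({
    while (i <= n) {
      ch <- chars[i]
      if (ch == "[") {
        j <- i + 1L
        while (j <= n && chars[j] != "]") j <- j + 1L
        if (j > n) stop("unclosed bracket atom")
        at <- .parse_bracket(paste0(chars[seq.int(i + 1L, j - 1L)], collapse = ""))
        idx <- add_atom(at$symbol, at$aromatic, at$charge, at$isotope,
                        at$hcount, at$chiral)
        if (prev > 0L) bond_between(prev, idx, pending)
        pending <- ""; prev <- idx; i <- j + 1L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
        if (two %in% c("Cl", "Br")) {
          idx <- add_atom(two, FALSE); i <- i + 2L
        } else {
          idx <- add_atom(ch, FALSE); i <- i + 1L
        }
        if (prev > 0L) bond_between(prev, idx, pending)
        pending <- ""; prev <- idx
      } else if (ch %in% .AROMATIC_SUBSET) {
        idx <- add_atom(toupper(ch), TRUE)
        if (prev > 0L) bond_between(prev, idx, pending)
        pending <- ""; prev <- idx; i <- i + 1L
      } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
        if (pending != "") stop("two consecutive bond symbols")
        pending <- ch; i <- i + 1L
      } else if (ch == "(") {
        if (prev == 0L) stop("branch before any atom")
        if (pending != "") stop("bond symbol before '('")
        stack <- c(stack, prev)
        branch_mark <- c(branch_mark, length(symbol))
        i <- i + 1L
      } else if (ch == ")") {
        if (length(stack) == 0L) stop("unmatched ')'")
        if (pending != "") stop("dangling bond symbol before ')'")
        if (branch_mark[length(branch_mark)] == length(symbol)) {
          stop("empty branch")
        }
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
        branch_mark <- branch_mark[-length(branch_mark)]
        i <- i + 1L
      } else if (grepl("^[0-9]$", ch) || ch == "%") {
        if (prev == 0L) stop("ring closure before any atom")
        if (ch == "%") {
          if (i + 2L > n || !grepl("^[0-9][0-9]$",
                                   paste0(chars[i + 1L], chars[i + 2L]))) {
            stop("malformed %NN ring closure")
          }
          num <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
        } else {
          num <- ch; i <- i + 1L
        }
        open <- rings[[num]]
        if (is.null(open)) {
          rings[[num]] <- list(atom = prev, bondsym = pending)
        } else {
          sym <- pending
          if (sym == "" && open$bondsym != "") sym <- open$bondsym
          if (sym != "" && open$bondsym != "" && sym != open$bondsym) {
            stop("conflicting ring-closure bond symbols")
          }
          bond_between(open$atom, prev, sym)
          rings[[num]] <- NULL
        }
        pending <- ""
      } else if (ch == ".") {
        if (pending != "") stop("bond symbol before '.'")
        prev <- 0L; i <- i + 1L
      } else {
        stop("unexpected character '", ch, "'")
      }
    }
    if (length(stack) > 0L) stop("unclosed branch")
    if (length(rings) > 0L) stop("unclosed ring bond")
    if (pending != "") stop("dangling bond symbol")
    if (length(symbol) == 0L) stop("no atoms")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) return(smi_fail(res))

  # duplicate bonds (e.g. C1CC1 plus an explicit closure on the same pair)
  if (length(b_a1) > 0L) {
    key <- paste(pmin(b_a1, b_a2), pmax(b_a1, b_a2))
    if (anyDuplicated(key)) return(smi_fail("duplicate bond"))
  }

  g <- list(
    ok = TRUE,
    symbol = symbol, aromatic = aromatic, charge = charge,
    isotope = isotope, hspec = hspec, chiral = chiral,
    bond = data.frame(a1 = b_a1, a2 = b_a2, order = b_ord,
                      aromatic = b_arom, stereo = b_stereo,
                      stringsAsFactors = FALSE)
  )
  g <- .smi_finish(g)
  if (!g$ok) return(g)
  class(g) <- "smigraph"
  g
}

.parse_bracket <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H([0-9]*))?(([+-])([0-9]*)|(\\+{2,})|(-{2,}))?(:[0-9]+)?$",
    body))[[1L]]
  if (length(m) == 0L) stop("malformed bracket atom [", body, "]")
  iso <- if (nzchar(m[2L])) as.integer(m[2L]) else NA_integer_
  raw <- m[3L]
  arom <- raw %in% .AROMATIC_SUBSET
  sym <- if (arom) {
    paste0(toupper(substr(raw, 1L, 1L)), substring(raw, 2L))
  } else raw
  if (!arom && !(sym %in% names(.ATOMIC_MASS)) )
    stop("unsupported element [", raw, "]")
  if (arom && !(raw %in% .AROMATIC_SUBSET) )
    stop("unsupported aromatic element [", raw, "]")
  h <- if (nzchar(m[5L])) {
    if (nzchar(m[6L])) as.integer(m[6L]) else 1L
  } else 0L
  chg <- 0L
  if (nzchar(m[7L])) {
    mag <- if (nzchar(m[9L])) as.integer(m[9L]) else 1L
    chg <- if (m[8L] == "+") mag else -mag
  } else if (nzchar(m[10L])) chg <- nchar(m[10L])
  else if (nzchar(m[11L])) chg <- -nchar(m[11L])
  list(symbol = sym, aromatic = arom, isotope = iso, hcount = h,
       charge = chg, chiral = if (is.na(m[4L]) || !nzchar(m[4L])) "" else m[4L])
}

# adjacency, implicit hydrogens, valence check, ring perception
.smi_finish <- function(g) {
  na <- length(g$symbol)
  nbr <- vector("list", na)
  bidx <- vector("list", na)
  nb <- nrow(g$bond)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      a1 <- g$bond$a1[k]; a2 <- g$bond$a2[k]
      nbr[[a1]] <- c(nbr[[a1]], a2); nbr[[a2]] <- c(nbr[[a2]], a1)
      bidx[[a1]] <- c(bidx[[a1]], k); bidx[[a2]] <- c(bidx[[a2]], k)
    }
  }
  g$nbr <- nbr; g$bidx <- bidx

  hcount <- integer(na)
  for (a in seq_len(na)) {
    if (!is.na(g$hspec[a])) {            # bracket atom: H count is explicit
      hcount[a] <- g$hspec[a]
      next
    }
    h <- .implied_bare_h(g$symbol[a], g$aromatic[a], g$bond, bidx[[a]])
    if (is.na(h)) {
      return(smi_fail(sprintf("valence too high for %s", g$symbol[a])))
    }
    hcount[a] <- h
    if (g$aromatic[a] && !(tolower(g$symbol[a]) %in% .AROMATIC_SUBSET)) {
      return(smi_fail("non-aromatizable element flagged aromatic"))
    }
  }
  g$hcount <- hcount

  g$ring_bond <- .ring_bonds(na, g$bond, nbr, bidx)
  g$ring_atom <- rep(FALSE, na)
  if (any(g$ring_bond)) {
    ra <- unique(c(g$bond$a1[g$ring_bond], g$bond$a2[g$ring_bond]))
    g$ring_atom[ra] <- TRUE
  }
  # an aromatic flag off-ring is malformed chemistry for our purposes
  if (any(g$aromatic & !g$ring_atom)) {
    return(smi_fail("aromatic atom outside of any ring"))
  }
  g
}

# ring bonds = non-bridge edges (iterative Tarjan bridge finding)
.ring_bonds <- function(na, bond, nbr, bidx) {
  nb <- nrow(bond)
  if (nb == 0L) return(logical(0))
  disc <- integer(na); low <- integer(na)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(na)) {
    if (disc[root] > 0L) next
    # stack frames: atom, parent-bond, next-neighbour-pointer
    st_atom <- root; st_pb <- 0L; st_ptr <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    depth <- 1L
    while (depth > 0L) {
      a <- st_atom[depth]; ptr <- st_ptr[depth]
      if (ptr <= length(nbr[[a]])) {
        st_ptr[depth] <- ptr + 1L
        b <- nbr[[a]][ptr]; k <- bidx[[a]][ptr]
        if (k == st_pb[depth]) next
        if (disc[b] > 0L) {
          low[a] <- min(low[a], disc[b])
          st_atom[depth] <- a
        } else {
          timer <- timer + 1L; disc[b] <- low[b] <- timer
          depth <- depth + 1L
          st_atom[depth] <- b; st_pb[depth] <- k; st_ptr[depth] <- 1L
        }
      } else {
        depth <- depth - 1L
        if (depth > 0L) {
          p <- st_atom[depth]
          low[p] <- min(low[p], low[a])
          if (low[a] > disc[p]) is_bridge[st_pb[depth + 1L]] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

.has_stereo <- function(g) {
  any(nzchar(g$chiral)) || any(nzchar(g$bond$stereo))
}

# molecular weight including implicit/explicit hydrogens
smi_mw <- function(g) {
  stopifnot(g$ok)
  m <- sum(.ATOMIC_MASS[g$symbol]) + sum(g$hcount) * .ATOMIC_MASS[["H"]]
  unname(m)
}

# number of aromatic rings = cyclomatic number of the aromatic-bond subgraph
smi_n_aromatic_rings <- function(g) {
  stopifnot(g$ok)
  keep <- g$bond$aromatic & g$ring_bond
  if (!any(keep)) return(0L)
  va <- sort(unique(c(g$bond$a1[keep], g$bond$a2[keep])))
  idx <- match(seq_along(g$symbol), va)
  # connected components over the aromatic subgraph
  parent <- seq_along(va)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in which(keep)) {
    r1 <- findp(idx[g$bond$a1[k]]); r2 <- findp(idx[g$bond$a2[k]])
    if (r1 != r2) parent[r1] <- r2
  }
  ncomp <- length(unique(vapply(seq_along(va), findp, 1L)))
  sum(keep) - length(va) + ncomp
}

# ---- SMILES writer ---------------------------------------------------------

.atom_token <- function(g, a) {
  sym <- g$symbol[a]
  arom <- g$aromatic[a]
  disp <- if (arom) tolower(sym) else sym
  bare_ok <- sym %in% .ORGANIC_SUBSET && g$charge[a] == 0L &&
    is.na(g$isotope[a]) && !nzchar(g$chiral[a])
  if (bare_ok) {
    # bare form is legal only when the reader would re-derive the same H count
    implied <- .implied_bare_h(sym, arom, g$bond, g$bidx[[a]])
    if (!is.na(implied) && implied == g$hcount[a]) return(disp)
  }
  h <- g$hcount[a]
  paste0("[",
         if (!is.na(g$isotope[a])) g$isotope[a] else "",
         disp, g$chiral[a],
         if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
         if (g$charge[a] > 0L) {
           if (g$charge[a] == 1L) "+" else paste0("+", g$charge[a])
         } else if (g$charge[a] < 0L) {
           if (g$charge[a] == -1L) "-" else paste0("-", -g$charge[a])
         } else "",
         "]")
}

.bond_token <- function(g, k) {
  if (g$bond$aromatic[k]) return("")
  ord <- g$bond$order[k]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  a1 <- g$bond$a1[k]; a2 <- g$bond$a2[k]
  # explicit single between two aromatic atoms (e.g. biphenyl)
  if (g$aromatic[a1] && g$aromatic[a2]) return("-")
  ""
}

#' Write a SMILES string from a molecular graph under a given atom order.
#'
#' DFS over the graph; `order` ranks atoms, the DFS starts at the top-ranked
#' atom of each component and visits neighbours in rank order. Shuffling
#' `order` therefore produces randomized-but-equivalent SMILES.
#'
#' Two passes with identical traversal: pass 1 classifies edges into tree vs
#' ring-closure edges and assigns each closure a digit at both endpoints;
#' pass 2 emits tokens. Closure digits are unique per closure (1..9, then
#' %NN), which sidesteps digit-reuse bookkeeping.
#' @keywords internal
#' @noRd
smi_write <- function(g, order = seq_along(g$symbol)) {
  stopifnot(g$ok)
  na <- length(g$symbol)
  rank <- integer(na); rank[order] <- seq_len(na)

  visited <- logical(na)
  closure <- vector("list", na)   # atom -> list(list(k, digit, sym))
  n_closure <- 0L
  comp_roots <- integer(0)
  closed_k <- integer(0)

  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  classify <- function(a, parent_bond) {
    visited[a] <<- TRUE
    ks <- g$bidx[[a]]; bs <- g$nbr[[a]]
    for (t in base::order(rank[bs])) {
      k <- ks[t]; b <- bs[t]
      if (k == parent_bond) next
      if (visited[b]) {
        if (!(k %in% closed_k)) {
          n_closure <<- n_closure + 1L
          if (n_closure > 99L) stop("more than 99 ring closures")
          sym <- .bond_token(g, k)
          rec <- list(k = k, digit = n_closure, sym = sym)
          closure[[a]] <<- c(closure[[a]], list(rec))
          closure[[b]] <<- c(closure[[b]], list(rec))
          closed_k <<- c(closed_k, k)
        }
      } else {
        classify(b, k)
      }
    }
  }
  for (root in order) {
    if (!visited[root]) {
      comp_roots <- c(comp_roots, root)
      classify(root, 0L)
    }
  }

  visited2 <- logical(na)
  emit <- function(a, parent_bond) {
    visited2[a] <<- TRUE
    piece <- .atom_token(g, a)
    for (x in closure[[a]]) piece <- paste0(piece, x$sym, digit_token(x$digit))
    closure_ks <- vapply(closure[[a]], function(x) x$k, 1L)
    kids_b <- integer(0); kids_k <- integer(0)
    ks <- g$bidx[[a]]; bs <- g$nbr[[a]]
    for (t in base::order(rank[bs])) {
      k <- ks[t]; b <- bs[t]
      if (k == parent_bond || k %in% closure_ks || visited2[b]) next
      kids_b <- c(kids_b, b); kids_k <- c(kids_k, k)
    }
    nk <- length(kids_b)
    if (nk > 0L) {
      for (j in seq_len(nk)) {
        btok <- .bond_token(g, kids_k[j])
        sub <- emit(kids_b[j], kids_k[j])
        piece <- if (j < nk) paste0(piece, "(", btok, sub, ")")
        else paste0(piece, btok, sub)
      }
    }
    piece
  }

  pieces <- vapply(comp_roots, function(root) emit(root, 0L), "")
  paste0(pieces, collapse = ".")
}

# ---- Bemis-Murcko scaffold -------------------------------------------------

# iteratively strip terminal atoms not held by a double/triple bond;
# returns atom index subset (empty when the molecule is acyclic)
.murcko_atoms <- function(g) {
  if (!any(g$ring_atom)) return(integer(0))
  keep <- rep(TRUE, length(g$symbol))
  repeat {
    changed <- FALSE
    for (a in which(keep)) {
      ks <- g$bidx[[a]]
      live <- ks[keep[g$bond$a1[ks]] & keep[g$bond$a2[ks]]]
      if (length(live) == 1L) {
        k <- live[1L]
        if (g$bond$order[k] < 2L || g$bond$aromatic[k]) {
          keep[a] <- FALSE; changed <- TRUE
        }
      } else if (length(live) == 0L && length(g$symbol) > 1L) {
        keep[a] <- FALSE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  which(keep)
}

# extract induced subgraph and rebuild derived fields
.smi_subgraph <- function(g, atoms) {
  sel <- sort(atoms)
  amap <- integer(length(g$symbol)); amap[sel] <- seq_along(sel)
  bk <- which(g$bond$a1 %in% sel & g$bond$a2 %in% sel)
  h <- list(
    ok = TRUE,
    symbol = g$symbol[sel], aromatic = g$aromatic[sel],
    charge = g$charge[sel], isotope = g$isotope[sel],
    hspec = rep(NA_integer_, length(sel)),  # recompute implicit H
    chiral = rep("", length(sel)),
    bond = data.frame(a1 = amap[g$bond$a1[bk]], a2 = amap[g$bond$a2[bk]],
                      order = g$bond$order[bk], aromatic = g$bond$aromatic[bk],
                      stereo = rep("", length(bk)), stringsAsFactors = FALSE)
  )
  # bracket atoms whose H count was explicit keep it minus nothing: stripping
  # only removes whole substituents, so [nH] etc. keep their hydrogens
  h$hspec <- ifelse(is.na(g$hspec[sel]), NA_integer_, g$hspec[sel])
  h <- .smi_finish(h)
  class(h) <- "smigraph"
  h
}

# ---- Morgan / extended-connectivity fingerprint ----------------------------

.MHASH <- 2147483647  # 2^31 - 1; doubles keep products below 2^53 exact

.mix <- function(acc, v) ((acc * 33) %% .MHASH + (v %% .MHASH)) %% .MHASH

#' ECFP-style fingerprint: circular atom environments of radius 0..r hashed
#' onto `nbits` bits; returned as a sorted vector of set-bit positions.
#' @keywords internal
#' @noRd
smi_morgan_bits <- function(g, radius = 2L, nbits = 2048L) {
  stopifnot(g$ok)
  na <- length(g$symbol)
  anum <- .ATOMIC_NUMBER[g$symbol]
  ids <- numeric(na)
  for (a in seq_len(na)) {
    acc <- 17
    acc <- .mix(acc, anum[[a]])
    acc <- .mix(acc, length(g$nbr[[a]]))
    acc <- .mix(acc, g$hcount[a])
    acc <- .mix(acc, g$charge[a] + 10)
    acc <- .mix(acc, as.integer(g$aromatic[a]))
    acc <- .mix(acc, as.integer(g$ring_atom[a]))
    ids[a] <- acc
  }
  all_ids <- ids
  if (radius >= 1L && na > 1L) {
    for (r in seq_len(radius)) {
      new_ids <- numeric(na)
      for (a in seq_len(na)) {
        ks <- g$bidx[[a]]; bs <- g$nbr[[a]]
        if (length(bs) == 0L) { new_ids[a] <- .mix(ids[a], r); next }
        bo <- ifelse(g$bond$aromatic[ks], 4L, g$bond$order[ks])
        pairs <- bo * .MHASH + ids[bs]            # order by (bond, id)
        o <- base::order(bo, ids[bs])
        acc <- .mix(ids[a], r)
        for (t in o) {
          acc <- .mix(acc, bo[t])
          acc <- .mix(acc, ids[bs[t]])
        }
        new_ids[a] <- acc
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(as.integer(all_ids %% nbits)))
}
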