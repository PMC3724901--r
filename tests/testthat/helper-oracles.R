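# Independent oracles used to validate the package implementations on
# small instances. These deliberately use different algorithms (explicit
# history enumeration, dense transfer matrices, Matrix::expm) from the
# production code paths.

# ---- brute-force deep-coalescence oracle -------------------------------
# Minimal extra lineages over ALL lineage-sorting histories: within every
# population-tree branch any subset/sequence of permissible coalescences
# (between gene-tree siblings) may occur; the cost of a history is
# sum over branches of (lineages exiting rootward - 1).

dc_oracle <- function(gene_tree, model, assignment) {
  stopifnot(inherits(gene_tree, "phylo"))
  ntip <- ape::Ntip(gene_tree)
  nn <- ntip + gene_tree$Nnode
  gpar <- integer(nn)
  gpar[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  phy <- model$phy
  sp_ntip <- ape::Ntip(phy)
  sp_nn <- sp_ntip + phy$Nnode
  sp_kids <- vector("list", sp_nn)
  for (k in seq_len(nrow(phy$edge))) {
    sp_kids[[phy$edge[k, 1]]] <- c(sp_kids[[phy$edge[k, 1]]],
                                   phy$edge[k, 2])
  }
  sp_root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  tipmap <- match(as.character(assignment[gene_tree$tip.label]),
                  phy$tip.label)

  # all exit sets reachable from a lineage set by merging siblings,
  # with no better cost than (|exit| - 1); returns named numeric vector
  # key -> min (|exit| - 1)
  closures <- function(S) {
    seen <- new.env(parent = emptyenv())
    out <- new.env(parent = emptyenv())
    rec <- function(S) {
      key <- paste(sort(S), collapse = ",")
      if (!is.null(seen[[key]])) return(invisible())
      seen[[key]] <- TRUE
      out[[key]] <- length(S) - 1L
      if (length(S) >= 2L) {
        for (i in seq_along(S)) for (j in seq_along(S)) {
          if (i < j && gpar[S[i]] != 0L && gpar[S[i]] == gpar[S[j]]) {
            rec(c(S[-c(i, j)], gpar[S[i]]))
          }
        }
      }
    }
    rec(S)
    keys <- ls(out)
    setNames(vapply(keys, function(k) out[[k]], numeric(1)), keys)
  }

  # returns named vector: exit-set key -> min cost of subtree incl. the
  # branch above this species node (except at the root, handled below)
  visit <- function(v) {
    if (v <= sp_ntip) {
      enter <- list(setNames(0, paste(sort(which(tipmap == v)),
                                      collapse = ",")))
      combos <- enter[[1]]
    } else {
      parts <- lapply(sp_kids[[v]], visit)
      combos <- parts[[1]]
      for (p in parts[-1]) {
        new <- c()
        for (k1 in names(combos)) for (k2 in names(p)) {
          ids <- c(as.integer(strsplit(k1, ",")[[1]]),
                   as.integer(strsplit(k2, ",")[[1]]))
          key <- paste(sort(ids), collapse = ",")
          val <- combos[[k1]] + p[[k2]]
          if (is.null(new[key]) || is.na(new[key]) || val < new[key]) {
            new[key] <- val
          }
        }
        combos <- new
      }
    }
    best <- c()
    for (k in names(combos)) {
      S <- as.integer(strsplit(k, ",")[[1]])
      cl <- closures(S)
      for (ek in names(cl)) {
        val <- combos[[k]] + if (v == sp_root) 0 else cl[[ek]]
        if (is.null(best[ek]) || is.na(best[ek]) || val < best[ek]) {
          best[ek] <- val
        }
      }
    }
    best
  }
  min(visit(sp_root))
}

# enumerate every labelled rooted binary topology on a label set, as
# Newick strings (3 labels -> 3, 4 -> 15, 5 -> 105)
all_topologies <- function(labels) {
  grow <- function(trees, lab) {
    unlist(lapply(trees, function(tr) {
      insert <- function(node) {
        here <- list(list(node, lab))
        if (!is.list(node) || length(node) == 1L) return(here)
        c(here,
          lapply(insert(node[[1]]), function(sub) list(sub, node[[2]])),
          lapply(insert(node[[2]]), function(sub) list(node[[1]], sub)))
      }
      insert(tr)
    }), recursive = FALSE)
  }
  trees <- list(labels[[1]])
  for (lab in labels[-1]) trees <- grow(trees, lab)
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", to_newick(node[[1]]), ":1,", to_newick(node[[2]]), ":1):1")
  }
  vapply(trees, function(tr) paste0(to_newick(tr), ";"), character(1))
}

# ---- DEC full-enumeration oracle ---------------------------------------
# Likelihood by explicit summation over every internal-node state and
# ordered cladogenetic scenario; transition matrices via Matrix::expm.

dec_oracle_scenarios <- function(mask, k) {
  occ <- which(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L) == 1L)
  if (length(occ) == 1L) return(list(left = mask, right = mask, prob = 1))
  L <- integer(0); R <- integer(0)
  for (a in occ) {
    bit <- bitwShiftL(1L, a - 1L)
    rest <- bitwAnd(mask, bitwNot(bit))
    L <- c(L, bit, rest, bit, mask); R <- c(R, rest, bit, mask, bit)
  }
  keep <- !duplicated(paste(L, R))
  L <- L[keep]; R <- R[keep]
  list(left = L, right = R, prob = rep(1 / length(L), length(L)))
}

dec_oracle_p <- function(model, params, older, younger) {
  ns <- length(model$states)
  P <- diag(ns)
  for (s in seq_along(model$strata)) {
    so <- model$strata[[s]]$older; sy <- model$strata[[s]]$younger
    a <- min(older, so); b <- max(younger, sy)
    if (a > b + 1e-12) {
      Q <- build_q(model, params, s)
      P <- P %*% as.matrix(Matrix::expm(Q * (a - b)))
    }
  }
  P
}

dec_oracle_loglik <- function(tree, ranges, model, params,
                              root_state = NULL) {
  k <- length(model$areas)
  states <- model$states
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  age <- pmax(model$root_age - depth, 0)
  kids <- lapply(seq_len(ntip + tree$Nnode),
                 function(v) tree$edge[tree$edge[, 1] == v, 2])
  tipmask <- as.integer(
    unclass(ranges)[tree$tip.label, model$areas, drop = FALSE] %*%
      bitwShiftL(1L, seq_len(k) - 1L))
  rec <- function(v, smask) {
    if (v <= ntip) return(as.numeric(smask == tipmask[v]))
    sc <- dec_oracle_scenarios(smask, k)
    tot <- 0
    for (i in seq_along(sc$prob)) {
      side <- numeric(2)
      for (s2 in 1:2) {
        ch <- kids[[v]][s2]
        start <- if (s2 == 1) sc$left[i] else sc$right[i]
        P <- dec_oracle_p(model, params, age[v], age[ch])
        si <- match(start, states)
        side[s2] <- sum(vapply(seq_along(states), function(j) {
          if (P[si, j] <= 0) 0 else P[si, j] * rec(ch, states[j])
        }, numeric(1)))
      }
      tot <- tot + sc$prob[i] * side[1] * side[2]
    }
    tot
  }
  root <- ntip + 1L
  keep <- if (is.null(root_state)) states[states != 0L] else root_state
  -log(sum(vapply(keep, function(s) rec(root, s), numeric(1))))
}

# ---- binary-character transfer-matrix oracle ---------------------------
# Marginal posterior at a node by enumerating all internal-node states.

asr_oracle_marginal <- function(tree, char, rate, node, bias = 0.5) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ints <- (ntip + 1L):nn
  P <- function(t) {
    ex <- exp(-rate * t)
    matrix(c(1 - bias * (1 - ex), bias * (1 - ex),
             (1 - bias) * (1 - ex), 1 - (1 - bias) * (1 - ex)),
           2, 2, byrow = TRUE)
  }
  st <- char$data[tree$tip.label]
  root <- ntip + 1L
  marg <- c(0, 0)
  grid <- expand.grid(rep(list(0:1), length(ints)))
  for (g in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[ints] <- as.integer(grid[g, ])
    pr <- c(1 - bias, bias)[s[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      Pt <- P(tree$edge.length[e])
      if (b <= ntip) {
        if (is.na(st[b])) next
        pr <- pr * Pt[s[a] + 1L, st[b] + 1L]
      } else {
        pr <- pr * Pt[s[a] + 1L, s[b] + 1L]
      }
    }
    if (node > ntip) {
      marg[s[node] + 1L] <- marg[s[node] + 1L] + pr
    }
  }
  marg / sum(marg)
}

# small shared fixtures ---------------------------------------------------
abc_regions <- c("A", "B", "C")
abc_model <- function(depths = c(2, 1), topo = "((A,B),C);",
                      samples = c(A = 1, B = 1, C = 1)) {
  divergence_model(topo, depths = depths, samples = samples,
                   regions = abc_regions)
}
abc_assignment <- function(counts = c(A = 1, B = 1, C = 1)) {
  assignment_from_counts(counts)
}
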