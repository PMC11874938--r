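# Independent oracles used by the test suite.  These are deliberately
# naive re-derivations (full dynamic programming, exhaustive subset
# search) kept separate from the package implementation they check.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Smith-Waterman local alignment score with affine gaps (Gotoh), plain R.
# Row-vectorized: X (gap in subject) uses only the previous row; Y (gap
# in query) is max_k(M[i,k] + k*ext) - open - j*ext, a cummax over the
# current row.
sw_local_score <- function(query, subject, mat = blosum62_matrix(),
                           gap_open = 11, gap_ext = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  if (m == 0 || n == 0) return(0)
  NEG <- -1e9
  M_prev <- numeric(n + 1)
  X_prev <- rep(NEG, n + 1)
  Y_prev <- rep(NEG, n + 1)
  best <- 0
  j_idx <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- mat[q[i], s]
    diag_best <- pmax(0, M_prev[j_idx], X_prev[j_idx], Y_prev[j_idx])
    M_cur <- c(0, diag_best + sub)
    X_cur <- c(NEG, pmax(M_prev[-1] - gap_open - gap_ext,
                         X_prev[-1] - gap_ext))
    run <- cummax(M_cur[j_idx] + j_idx * gap_ext)
    Y_cur <- c(NEG, run - gap_open - (j_idx + 1) * gap_ext)
    best <- max(best, max(M_cur))
    M_prev <- M_cur; X_prev <- X_cur; Y_prev <- Y_cur
  }
  best
}

# best translated-search score over all six frames, aligning each
# stop-free segment independently (mirrors the search contract, with an
# independent aligner)
oracle_best_score <- function(query, subject_nt) {
  frames <- peptidetect::six_frame_translate(subject_nt)
  best <- 0
  for (fr in frames) {
    for (seg in strsplit(fr, "*", fixed = TRUE)[[1]]) {
      if (nchar(seg) >= 1) {
        best <- max(best, sw_local_score(query, seg))
      }
    }
  }
  best
}

# exhaustive minimum Dollo losses: smallest set of edges such that every
# absent tip is below a chosen edge and no present tip is
dollo_brute_force <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  st <- setNames(rep("unknown", ntip), tree$tip.label)
  st[names(states)] <- states
  n_edges <- nrow(tree$edge)
  # edges on the root path of each tip
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(n_edges)
  root <- ntip + 1L
  path_edges <- function(tip) {
    out <- integer()
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      out <- c(out, e)
      node <- tree$edge[e, 1]
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_edges)
  absent <- which(st == "absent")
  present <- which(st == "present")
  if (length(absent) == 0) return(0L)
  feasible <- function(sel) {
    all(vapply(absent, function(t) any(paths[[t]] %in% sel), logical(1))) &&
      !any(vapply(present, function(t) any(paths[[t]] %in% sel),
                  logical(1)))
  }
  for (k in 1:n_edges) {
    combos <- utils::combn(n_edges, k)
    for (c_i in seq_len(ncol(combos))) {
      if (feasible(combos[, c_i])) return(k)
    }
  }
  NA_integer_
}

# random rooted binary tree with given tip labels
random_tree <- function(ntip) {
  ape::rtree(ntip, rooted = TRUE, br = NULL,
             tip.label = paste0("t", seq_len(ntip)))
}

# interval clustering oracle for locus merging: single-linkage on
# intervals with gap <= max_gap
cluster_intervals <- function(starts, ends, max_gap) {
  o <- order(starts)
  cl <- integer(length(starts))
  cur <- 0L
  cur_end <- -Inf
  for (i in o) {
    if (starts[i] - cur_end > max_gap) {
      cur <- cur + 1L
      cur_end <- ends[i]
    } else {
      cur_end <- max(cur_end, ends[i])
    }
    cl[i] <- cur
  }
  cl
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
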