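# Independent oracles and small fixture builders used across tests.
# Each oracle is a deliberately naive re-derivation (explicit loops, direct
# counting, closed forms) that never calls the code path it checks.

# Position-by-position window score using Biostrings' BLOSUM62 directly,
# with the X-scores-0 rule applied per character.
oracle_window_score <- function(window, template) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- strsplit(window, "")[[1]]
  t <- strsplit(template, "")[[1]]
  s <- 0
  for (i in seq_along(w)) {
    if (w[i] %in% aa && t[i] %in% aa) s <- s + e$BLOSUM62[w[i], t[i]]
  }
  s
}

# Brute-force double loop over every window of every protein.
oracle_scan_scores <- function(proteome, template) {
  x <- nchar(template)
  out <- NULL
  for (i in seq_len(nrow(proteome))) {
    L <- nchar(proteome$sequence[i])
    if (L < x) next
    for (s in seq_len(L - x + 1)) {
      w <- substr(proteome$sequence[i], s, s + x - 1)
      out <- rbind(out, data.frame(protein_id = proteome$protein_id[i],
                                   start = s,
                                   score = oracle_window_score(w, template)))
    }
  }
  out
}

# Literal pair counting for clue-LR estimation: walk the TP and TN lists and
# count pairs carrying each (method, clue, value).
oracle_clue_lr <- function(observations, pairs, lr_cap = 1e6) {
  okey <- paste(pmin(observations$protein_a, observations$protein_b),
                pmax(observations$protein_a, observations$protein_b))
  tp_keys <- paste(pairs$positives$protein_a, pairs$positives$protein_b)
  tn_keys <- paste(pairs$negatives$protein_a, pairs$negatives$protein_b)
  grp <- paste(observations$method, observations$clue_id,
               observations$value)
  out <- NULL
  for (g in unique(grp)) {
    gkeys <- unique(okey[grp == g])
    n_tp <- 0; n_tn <- 0
    for (k in tp_keys) if (k %in% gkeys) n_tp <- n_tp + 1
    for (k in tn_keys) if (k %in% gkeys) n_tn <- n_tn + 1
    p_tp <- n_tp / pairs$N_TP
    p_tn <- n_tn / pairs$N_TN
    lr <- if (p_tn == 0) lr_cap else min(p_tp / p_tn, lr_cap)
    out <- rbind(out, data.frame(group = g, n_TP = n_tp, n_TN = n_tn,
                                 lr = lr, stringsAsFactors = FALSE))
  }
  out[order(out$group), ]
}

# Concordance AUC: fraction of (positive, negative) score pairs ranked
# correctly, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Analytic ASA of two intersecting spheres (expanded radii R1, R2, centre
# distance d): each sphere loses the cap buried inside the other.
oracle_two_sphere_asa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * max(0, h1),
    4 * pi * R2^2 - 2 * pi * R2 * max(0, h2))
}

# Minimal single-chain structure with one atom per residue.
make_point_structure <- function(xyz, chain = "A", element = "C") {
  n <- nrow(xyz)
  structure(list(atoms = data.frame(
    chain = chain, resno = seq_len(n), insert = "", resname = "ALA",
    atom = "CA", element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)), class = "pdb_structure")
}

# Two-chain structure from two coordinate blocks.
make_two_chain_structure <- function(xyz_a, xyz_b) {
  a <- make_point_structure(xyz_a, "A")$atoms
  b <- make_point_structure(xyz_b, "B")$atoms
  structure(list(atoms = rbind(a, b)), class = "pdb_structure")
}

random_rotation <- function() {
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

transform_structure <- function(st, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(rot)
  st$atoms$x <- xyz[, 1] + shift[1]
  st$atoms$y <- xyz[, 2] + shift[2]
  st$atoms$z <- xyz[, 3] + shift[3]
  st
}

# Small random proteome for property tests.
random_proteome <- function(n, len_min = 20, len_max = 60) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(len_min:len_max, n, replace = TRUE)
  data.frame(protein_id = sprintf("RP%03d", seq_len(n)),
             sequence = vapply(lens, function(L) {
               paste(sample(aa, L, replace = TRUE), collapse = "")
             }, character(1)),
             length = lens, stringsAsFactors = FALSE)
}
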