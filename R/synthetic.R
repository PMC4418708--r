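# Synthetic-data generators: every input the pipeline consumes can be built
# from one seeded configuration, so the whole package installs, runs and is
# tested without any external download.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

#' Synthetic-study configuration
#'
#' One seeded configuration drives every generator.  The clue frequencies
#' are the planted study conditions: a clue appears on a true-positive pair
#' with probability `tp` and on a true-negative pair with probability `tn`,
#' so the expected likelihood ratio of e.g. the default PRD/motif match clue
#' is 0.5 / 0.05 = 10.  Setting `signal = FALSE` copies every `tp` parameter
#' onto its `tn` counterpart, which removes all association between clues
#' and labels (the permutation-null condition).
#'
#' @param seed Mandatory integer master seed; each sub-generator derives its
#'   own independent stream from it.
#' @param n_proteins,len_range Proteome size and residue-length range.
#' @param motifs Motif strings planted into the proteome.
#' @param n_elm_classes Number of consensus classes (at most like `motifs`).
#' @param n_TP,n_TN Training-set sizes.
#' @param p_match Named list with `prd_motif` and `struct` elements, each
#'   `c(tp = , tn = )`: probability that a pair carries a candidate
#'   interface from that method.
#' @param p_diso,p_consv `c(tp =, tn =)`: probability that a carried
#'   interface's motif is disordered / locally conserved.
#' @param p_psd1 `c(tp =, tn =)`: probability that a struct interface falls
#'   in PSD bin P1 (else P2).
#' @param sim_weights List with `tp` and `tn` weight vectors over similarity
#'   bins B1..B4.
#' @param ns_meanlog,ns_sdlog Log-normal parameters of the non-structural
#'   LR, `c(tp =, tn =)` for the meanlog.
#' @param signal Set FALSE to equalize all TP/TN frequencies.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_proteins = 24,
                         len_range = c(350, 500),
                         motifs = c("PPLPARKA", "KRSLPVF", "DEVDSGW"),
                         n_elm_classes = 3,
                         n_TP = 2000, n_TN = 2000,
                         p_match = list(prd_motif = c(tp = 0.5, tn = 0.05),
                                        struct = c(tp = 0.3, tn = 0.03)),
                         p_diso = c(tp = 0.7, tn = 0.3),
                         p_consv = c(tp = 0.6, tn = 0.3),
                         p_psd1 = c(tp = 0.7, tn = 0.3),
                         sim_weights = list(
                           tp = c(B1 = 0.10, B2 = 0.20, B3 = 0.30, B4 = 0.40),
                           tn = c(B1 = 0.02, B2 = 0.08, B3 = 0.30, B4 = 0.60)),
                         ns_meanlog = c(tp = log(20), tn = 0),
                         ns_sdlog = 1,
                         signal = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(unlist(p_match), p_diso, p_consv, p_psd1)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_proteins < 1) stop("n_proteins must be at least 1")
  if (n_TP < 1 || n_TN < 1) stop("n_TP and n_TN must be at least 1")
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              len_range = len_range, motifs = motifs,
              n_elm_classes = min(n_elm_classes, length(motifs)),
              n_TP = n_TP, n_TN = n_TN, p_match = p_match, p_diso = p_diso,
              p_consv = p_consv, p_psd1 = p_psd1, sim_weights = sim_weights,
              ns_meanlog = ns_meanlog, ns_sdlog = ns_sdlog,
              signal = isTRUE(signal))
  if (!cfg$signal) {
    cfg$p_match <- lapply(cfg$p_match, function(p) c(tp = unname(p["tp"]),
                                                     tn = unname(p["tp"])))
    cfg$p_diso["tn"] <- cfg$p_diso["tp"]
    cfg$p_consv["tn"] <- cfg$p_consv["tp"]
    cfg$p_psd1["tn"] <- cfg$p_psd1["tp"]
    cfg$sim_weights$tn <- cfg$sim_weights$tp
    cfg$ns_meanlog["tn"] <- cfg$ns_meanlog["tp"]
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a toy proteome with planted motifs
#'
#' Sequences are i.i.d. uniform over the 20 amino acids; the configured
#' motif strings are spliced in at recorded positions (motif `j` goes into
#' protein `j`, cycling, for the first half of the proteome).
#'
#' @param config A [synth_config()].
#' @return List with `proteome` (data.frame as from [read_fasta()]) and
#'   `ledger` (data.frame `protein_id`, `start`, `end`, `motif` of planted
#'   ground truth).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(sub_seed(config$seed, "proteome"), {
    n <- config$n_proteins
    lens <- sample(config$len_range[1]:config$len_range[2], n, replace = TRUE)
    ids <- sprintf("SYNP%04d", seq_len(n))
    seqs <- vapply(lens, function(L) {
      paste(sample(.aa20, L, replace = TRUE), collapse = "")
    }, character(1))
    carriers <- seq_len(max(1, floor(n / 2)))
    led <- NULL
    for (i in carriers) {
      motif <- config$motifs[(i - 1) %% length(config$motifs) + 1]
      w <- nchar(motif)
      if (w > lens[i]) stop("planted motif longer than protein ", ids[i])
      at <- sample(seq_len(lens[i] - w + 1), 1)
      substr(seqs[i], at, at + w - 1) <- motif
      led <- rbind(led, data.frame(protein_id = ids[i], start = at,
                                   end = at + w - 1, motif = motif,
                                   stringsAsFactors = FALSE))
    }
    list(proteome = data.frame(protein_id = ids, sequence = seqs,
                               length = nchar(seqs),
                               stringsAsFactors = FALSE),
         ledger = led)
  })
}

#' Generate ELM-style classes matching the planted motifs
#'
#' Each class's consensus pattern is its planted motif with two interior
#' positions wildcarded, so the pattern matches the planted instances and,
#' occasionally, background sequence.
#'
#' @param config A [synth_config()].
#' @return Data.frame with `class_id`, `family_id`, `pattern`.
#' @export
generate_elm_classes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$n_elm_classes
  motifs <- config$motifs[seq_len(k)]
  pats <- vapply(motifs, function(m) {
    p <- strsplit(m, "")[[1]]
    p[c(2, min(4, length(p)))] <- "."
    paste(p, collapse = "")
  }, character(1))
  data.frame(class_id = sprintf("SYNCLS%02d", seq_len(k)),
             family_id = sprintf("PF%05d", 90000 + seq_len(k)),
             pattern = unname(pats), stringsAsFactors = FALSE)
}

# Map k in 1..choose(m, 2) to the k-th unordered index pair of 1..m
# (column-major upper triangle), vectorized via cumulative pair counts.
index_to_pair <- function(k, m) {
  ends <- cumsum(seq_len(m - 1))     # pairs ending at column j+1
  j <- findInterval(k - 1, ends) + 1L
  i <- k - c(0, ends)[j]
  cbind(i, j + 1L)
}

#' Generate TP/TN pair sets with planted clue frequencies
#'
#' Abstract protein ids are paired without replacement; each true-positive
#' pair independently carries a candidate interface from each method with
#' probability `p_match[[method]]["tp"]` (analogously for true negatives),
#' and a carried interface draws its class / PSD bin / similarity bin /
#' disorder / conservation values from the configured TP or TN
#' distributions.  Non-structural LRs are drawn log-normally.
#'
#' @param config A [synth_config()].
#' @return List with `pairs` ([pair_set()]), `matches` (match data.frame),
#'   `ns` ([ns_table()]).
#' @export
generate_training_sets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_tp <- config$n_TP; n_tn <- config$n_TN
  need <- n_tp + n_tn
  m <- max(4, ceiling((1 + sqrt(1 + 9.6 * need)) / 2))
  with_seed(sub_seed(config$seed, "training_sets"), {
    idx <- sample.int(choose(m, 2), need)
    ij <- index_to_pair(idx, m)
    ids <- sprintf("PAIRP%05d", seq_len(m))
    a <- ids[ij[, 1]]; b <- ids[ij[, 2]]
    tp <- data.frame(protein_a = a[seq_len(n_tp)],
                     protein_b = b[seq_len(n_tp)], stringsAsFactors = FALSE)
    tn <- data.frame(protein_a = a[n_tp + seq_len(n_tn)],
                     protein_b = b[n_tp + seq_len(n_tn)],
                     stringsAsFactors = FALSE)
    pairs <- pair_set(tp, tn)
    class_ids <- sprintf("SYNCLS%02d", seq_len(config$n_elm_classes))
    template_ids <- sprintf("SYNTPL%02d", seq_len(2))

    draw_matches <- function(pp, which) {
      n <- nrow(pp)
      out <- NULL
      has_prd <- rbinom(n, 1, config$p_match$prd_motif[which]) == 1
      if (any(has_prd)) {
        np <- sum(has_prd)
        out <- rbind(out, data.frame(
          protein_a = pp$protein_a[has_prd], protein_b = pp$protein_b[has_prd],
          method = "prd_motif", source = NA_character_,
          class = sample(class_ids, np, replace = TRUE),
          psd = NA_character_, sim = NA_character_,
          diso = rbinom(np, 1, config$p_diso[which]) == 1,
          consv = rbinom(np, 1, config$p_consv[which]) == 1,
          stringsAsFactors = FALSE))
      }
      has_st <- rbinom(n, 1, config$p_match$struct[which]) == 1
      if (any(has_st)) {
        ns <- sum(has_st)
        out <- rbind(out, data.frame(
          protein_a = pp$protein_a[has_st], protein_b = pp$protein_b[has_st],
          method = "struct",
          source = sample(template_ids, ns, replace = TRUE),
          class = NA_character_,
          psd = ifelse(rbinom(ns, 1, config$p_psd1[which]) == 1, "P1", "P2"),
          sim = sample(names(config$sim_weights[[which]]), ns, replace = TRUE,
                       prob = config$sim_weights[[which]]),
          diso = rbinom(ns, 1, config$p_diso[which]) == 1,
          consv = rbinom(ns, 1, config$p_consv[which]) == 1,
          stringsAsFactors = FALSE))
      }
      out
    }
    matches <- rbind(draw_matches(pairs$positives, "tp"),
                     draw_matches(pairs$negatives, "tn"))
    if (is.null(matches)) {
      matches <- data.frame(protein_a = character(), protein_b = character(),
                            method = character(), source = character(),
                            class = character(), psd = character(),
                            sim = character(), diso = logical(),
                            consv = logical(), stringsAsFactors = FALSE)
    }
    ns_lr <- c(rlnorm(n_tp, config$ns_meanlog["tp"], config$ns_sdlog),
               rlnorm(n_tn, config$ns_meanlog["tn"], config$ns_sdlog))
    ns <- ns_table(data.frame(
      protein_a = c(pairs$positives$protein_a, pairs$negatives$protein_a),
      protein_b = c(pairs$positives$protein_b, pairs$negatives$protein_b),
      lr = ns_lr, stringsAsFactors = FALSE))
    list(pairs = pairs, matches = matches, ns = ns)
  })
}

#' Generate an idealized PRD-peptide complex
#'
#' The PRD is a CA+CB pseudo-helix (chain A), the peptide an extended CA+CB
#' strand (chain B) translated so that the minimum atom-atom distance to the
#' PRD equals `gap` exactly.  Idealized geometry (3.8 A CA spacing) is
#' adequate because only interatomic distances and ASA matter downstream.
#'
#' @param prd_size PRD residue count.
#' @param peptide_seq Peptide sequence (5-35 residues).
#' @param gap Minimum atom-atom distance between the chains, in Angstrom.
#' @param template_id Identifier for the resulting template.
#' @return List with `structure` (`pdb_structure`), `template`
#'   (`template_complex`), `peptide_seq` and `pdb_lines`.
#' @export
generate_toy_complex <- function(prd_size = 18, peptide_seq = "PPLPARK",
                                 gap = 4.0, template_id = "SYNTPL01") {
  pl <- nchar(peptide_seq)
  if (pl < 5 || pl > 35) stop("peptide length must be in [5, 35]")
  if (gap <= 0) stop("gap must be positive")
  i <- seq_len(prd_size)
  ang <- i * 100 * pi / 180
  prd <- data.frame(
    chain = "A", resno = rep(i, each = 2), insert = "",
    resname = rep(.aa3[sample_stable_aa(prd_size)], each = 2),
    atom = rep(c("CA", "CB"), prd_size), element = "C",
    x = as.vector(rbind(2.3 * cos(ang), 3.4 * cos(ang))),
    y = as.vector(rbind(2.3 * sin(ang), 3.4 * sin(ang))),
    z = rep(1.5 * i, each = 2), stringsAsFactors = FALSE)
  j <- seq_len(pl)
  zc <- 1.5 * (prd_size + 1) / 2
  pep0 <- data.frame(
    chain = "B", resno = rep(j, each = 2), insert = "",
    resname = rep(.aa3[strsplit(toupper(peptide_seq), "")[[1]]], each = 2),
    atom = rep(c("CA", "CB"), pl), element = "C",
    x = rep(3.8 * (j - (pl + 1) / 2), each = 2),
    y = as.vector(rbind(rep(0, pl), rep(1.5, pl))),
    z = zc, stringsAsFactors = FALSE)
  min_dist <- function(t) {
    px <- pep0$x + t
    d2 <- outer(prd$x, px, "-")^2 + outer(prd$y, pep0$y, "-")^2 +
      outer(prd$z, pep0$z, "-")^2
    sqrt(min(d2))
  }
  t0 <- uniroot(function(t) min_dist(t) - gap, c(0, 200), tol = 1e-10)$root
  pep0$x <- pep0$x + t0
  st <- base::structure(list(atoms = rbind(prd, pep0)),
                        class = "pdb_structure")
  tpl <- template_complex(st, template_id, prd_chain = "A",
                          peptide_chain = "B")
  list(structure = st, template = tpl, peptide_seq = toupper(peptide_seq),
       pdb_lines = write_pdb(st))
}

# Deterministic residue-name assignment for toy PRDs (not RNG-dependent).
sample_stable_aa <- function(n) {
  rep_len(c("L", "V", "A", "S", "T", "K", "E", "D", "F", "G"), n)
}

#' Generate disorder tracks, ortholog MSAs, structural alignments and NS
#' evidence for a toy proteome
#'
#' Planted motif residues get disorder scores around 0.7 and near-invariant
#' alignment columns; background residues get scores around 0.3 and heavily
#' substituted columns.  Structural alignments map template PRD residues
#' onto candidate models identically, with PSD values drawn uniformly on
#' [0, 0.8] (so both bins and the reject region occur).
#'
#' @param proteome,ledger From [generate_proteome()].
#' @param config A [synth_config()].
#' @param templates Optional list of `template_complex` objects to emit
#'   alignments for.
#' @param msa_depth Rows per ortholog alignment.
#' @return List with `disorder` (named list of score vectors), `msas`
#'   (named list of character matrices), `alignments` (list of
#'   `struct_alignment`).
#' @export
generate_tracks_and_msa <- function(proteome, ledger, config,
                                    templates = list(), msa_depth = 8) {
  stopifnot(inherits(config, "synth_config"))
  clip01 <- function(x) pmin(1, pmax(0, x))
  planted <- function(id) {
    rows <- ledger[ledger$protein_id == id, , drop = FALSE]
    pos <- integer(0)
    if (nrow(rows) > 0) {
      pos <- unlist(mapply(seq, rows$start, rows$end, SIMPLIFY = FALSE))
    }
    pos
  }
  with_seed(sub_seed(config$seed, "tracks"), {
    disorder <- lapply(seq_len(nrow(proteome)), function(i) {
      L <- proteome$length[i]
      sc <- clip01(rnorm(L, 0.3, 0.08))
      pos <- planted(proteome$protein_id[i])
      sc[pos] <- clip01(rnorm(length(pos), 0.7, 0.08))
      sc
    })
    names(disorder) <- proteome$protein_id

    msas <- lapply(seq_len(nrow(proteome)), function(i) {
      hum <- strsplit(proteome$sequence[i], "")[[1]]
      L <- length(hum)
      pos <- planted(proteome$protein_id[i])
      p_sub <- rep(0.5, L); p_sub[pos] <- 0.02
      p_gap <- rep(0.10, L); p_gap[pos] <- 0
      rows <- lapply(seq_len(msa_depth - 1), function(r) {
        row <- hum
        sub <- runif(L) < p_sub
        row[sub] <- sample(.aa20, sum(sub), replace = TRUE)
        gap <- runif(L) < p_gap
        row[gap] <- "-"
        row
      })
      m <- do.call(rbind, c(list(hum), rows))
      rownames(m) <- c(proteome$protein_id[i],
                       sprintf("%s_orth%02d", proteome$protein_id[i],
                               seq_len(msa_depth - 1)))
      m
    })
    names(msas) <- proteome$protein_id

    alignments <- list()
    if (length(templates) > 0) {
      k <- 0
      for (tpl in templates) {
        at <- tpl$structure$atoms
        prd_res <- unique(residue_refs(at[at$chain == tpl$prd_chain, ]))
        for (pid in proteome$protein_id) {
          k <- k + 1
          alignments[[k]] <- struct_alignment(
            tpl$template_id, pid, psd = runif(1, 0, 0.8),
            correspondence = setNames(prd_res, prd_res))
        }
      }
    }
    list(disorder = disorder, msas = msas, alignments = alignments)
  })
}

#' Write a complete synthetic input bundle
#'
#' Generates the proteome, classes, domain annotations, template complexes
#' (PDB + metadata), candidate-model PDBs, disorder TSV, per-protein MSAs,
#' structural-alignment TSV, TP/TN pair lists over the toy proteome and an
#' NS table, and writes them under `out_dir` in the formats the pipeline
#' readers consume.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of the paths written, invisibly.
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "msa"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "templates"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)

  gp <- generate_proteome(config)
  proteome <- gp$proteome; ledger <- gp$ledger
  classes <- generate_elm_classes(config)

  # templates: one per class motif (up to 2), peptide = planted motif
  tpl_seqs <- substr(config$motifs[seq_len(min(2, length(config$motifs)))],
                     1, 7)
  templates <- lapply(seq_along(tpl_seqs), function(k) {
    generate_toy_complex(prd_size = 18, peptide_seq = tpl_seqs[k],
                         gap = 4.0,
                         template_id = sprintf("SYNTPL%02d", k))
  })

  tr <- generate_tracks_and_msa(proteome, ledger, config,
                                templates = lapply(templates, `[[`,
                                                   "template"))

  # domain annotations: non-carrier proteins carry the PRD families
  n <- nrow(proteome)
  prd_proteins <- proteome$protein_id[(floor(n / 2) + 1):n]
  fam <- classes$family_id[rep_len(seq_len(nrow(classes)),
                                   length(prd_proteins))]
  domains <- data.frame(protein_id = prd_proteins, family_id = fam,
                        start = 1,
                        end = pmin(60, proteome$length[match(
                          prd_proteins, proteome$protein_id)]),
                        stringsAsFactors = FALSE)

  # TP pairs: planted motif carrier x matching PRD carrier; TN: other pairs
  with_seed(sub_seed(config$seed, "bundle_pairs"), {
    carrier_class <- setNames(
      sprintf("SYNCLS%02d",
              (seq_along(ledger$protein_id) - 1) %% nrow(classes) + 1),
      ledger$protein_id)
    tp <- NULL
    for (mc in names(carrier_class)) {
      fam_id <- classes$family_id[classes$class_id == carrier_class[mc]]
      partners <- domains$protein_id[domains$family_id == fam_id]
      if (length(partners) > 0) {
        tp <- rbind(tp, data.frame(protein_a = mc,
                                   protein_b = partners,
                                   stringsAsFactors = FALSE))
      }
    }
    tp <- canonicalize_pairs(tp)
    all_pairs <- t(utils::combn(proteome$protein_id, 2))
    all_keys <- pair_key(all_pairs[, 1], all_pairs[, 2])
    tn_pool <- all_pairs[!all_keys %in% pair_key(tp$protein_a,
                                                 tp$protein_b), ,
                         drop = FALSE]
    tn_idx <- sample(nrow(tn_pool), min(nrow(tn_pool), 6 * nrow(tp)))
    tn <- data.frame(protein_a = tn_pool[tn_idx, 1],
                     protein_b = tn_pool[tn_idx, 2],
                     stringsAsFactors = FALSE)
    pairs <- pair_set(tp, tn)
    ns <- ns_table(data.frame(
      protein_a = c(pairs$positives$protein_a, pairs$negatives$protein_a),
      protein_b = c(pairs$positives$protein_b, pairs$negatives$protein_b),
      lr = c(rlnorm(pairs$N_TP, config$ns_meanlog["tp"], config$ns_sdlog),
             rlnorm(pairs$N_TN, config$ns_meanlog["tn"], config$ns_sdlog)),
      stringsAsFactors = FALSE))
  })

  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    elm_classes = file.path(out_dir, "elm_classes.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    disorder = file.path(out_dir, "disorder.tsv"),
    templates_meta = file.path(out_dir, "templates", "templates.tsv"),
    struct_alignments = file.path(out_dir, "struct_alignments.tsv"),
    tp_pairs = file.path(out_dir, "tp_pairs.tsv"),
    tn_pairs = file.path(out_dir, "tn_pairs.tsv"),
    ns = file.path(out_dir, "ns.tsv"),
    msa_dir = file.path(out_dir, "msa"),
    model_dir = file.path(out_dir, "models"),
    ledger = file.path(out_dir, "planted_motifs.tsv"))

  write_fasta(proteome, paths$proteome)
  write_elm_classes(classes, paths$elm_classes)
  write_tsv(domains, paths$domains)
  write_disorder(tr$disorder, paths$disorder)
  write_tsv(ledger, paths$ledger)
  for (id in names(tr$msas)) {
    m <- tr$msas[[id]]
    write_fasta(data.frame(protein_id = rownames(m),
                           sequence = apply(m, 1, paste, collapse = ""),
                           stringsAsFactors = FALSE),
                file.path(paths$msa_dir, paste0(id, ".fasta")))
  }
  meta <- do.call(rbind, lapply(templates, function(t) {
    pdb_path <- file.path(out_dir, "templates",
                          paste0(t$template$template_id, ".pdb"))
    writeLines(t$pdb_lines, pdb_path)
    data.frame(template_id = t$template$template_id,
               pdb = basename(pdb_path), prd_chain = "A",
               peptide_chain = "B", peptide_seq = t$peptide_seq,
               multimer = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv(meta, paths$templates_meta)
  # candidate models: jittered copies of each template's PRD chain, one per
  # protein that has a structural alignment
  with_seed(sub_seed(config$seed, "models"), {
    for (a in tr$alignments) {
      tpl <- templates[[match(a$template_id, meta$template_id)]]
      at <- tpl$structure$atoms
      at <- at[at$chain == tpl$template$prd_chain, , drop = FALSE]
      at$x <- at$x + rnorm(nrow(at), 0, 0.05)
      at$y <- at$y + rnorm(nrow(at), 0, 0.05)
      at$z <- at$z + rnorm(nrow(at), 0, 0.05)
      model_path <- file.path(paths$model_dir,
                              paste0(a$protein_id, "_", a$template_id,
                                     ".pdb"))
      write_pdb(base::structure(list(atoms = at), class = "pdb_structure"),
                model_path)
    }
  })
  write_struct_alignments(tr$alignments, paths$struct_alignments)
  write_pair_set(pairs, paths$tp_pairs, paths$tn_pairs)
  write_ns_table(ns, paths$ns)
  invisible(paths)
}
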