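# End-to-end pipeline: scan -> features -> structure filters -> train ->
# combine -> flag, driven by one auditable configuration holding every
# numeric constant.

#' Pipeline run configuration
#'
#' Collects the input paths and every numeric threshold of the method in one
#' place.  Defaults are the published operating points: 4.5 A contact
#' distance, 10 A^2 surface ASA, 75\% interface coverage, PSD bins at
#' 0.3 / 0.65, window-scan retention at the top 0.05\%, disorder cutoff 0.5,
#' 31-residue conservation window, strong-prediction LR 600.
#'
#' @param proteome,elm_classes,domains,disorder,msa_dir,templates_meta,
#'   struct_alignments,model_dir,tp_pairs,tn_pairs,ns Input paths (see the
#'   corresponding readers).
#' @param out_dir Output directory for predictions and the run log.
#' @param distance_cutoff,asa_threshold,coverage_min,top_fraction,
#'   disorder_cutoff,consv_window,strong_threshold,alpha,lr_cap Numeric
#'   parameters.
#' @param policy Per-pair aggregation policy, `"max"` or `"product"`.
#' @param seed Seed forwarded to seeded steps.
#' @return List of class `run_config`.
#' @export
run_config <- function(proteome, elm_classes, domains, disorder, msa_dir,
                       templates_meta, struct_alignments, model_dir,
                       tp_pairs, tn_pairs, ns, out_dir = ".",
                       distance_cutoff = 4.5, asa_threshold = 10,
                       coverage_min = 0.75, top_fraction = 5e-4,
                       disorder_cutoff = 0.5, consv_window = 31,
                       strong_threshold = 600, alpha = 0, lr_cap = 1e6,
                       policy = "max", seed = 1) {
  cfg <- as.list(environment())
  num <- c("distance_cutoff", "asa_threshold", "coverage_min",
           "top_fraction", "disorder_cutoff", "consv_window",
           "strong_threshold")
  if (any(unlist(cfg[num]) <= 0)) stop("thresholds must be positive")
  if (!policy %in% c("max", "product")) {
    stop("policy must be 'max' or 'product'")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key-value run configuration file
#'
#' One `key<TAB>value` or `key=value` entry per line; `#` comments ignored.
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("dmi_missing_input", "error")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- as.list(vals)
  names(args) <- keys
  num <- suppressWarnings(as.numeric(vals))
  args[!is.na(num)] <- num[!is.na(num)]
  path_keys <- c("proteome", "elm_classes", "domains", "disorder",
                 "msa_dir", "templates_meta", "struct_alignments",
                 "model_dir", "tp_pairs", "tn_pairs", "ns", "out_dir")
  base <- dirname(normalizePath(path))
  for (k in intersect(names(args), path_keys)) {
    if (!grepl("^/", args[[k]])) args[[k]] <- file.path(base, args[[k]])
  }
  do.call(run_config, args)
}

#' Read template complexes from a metadata TSV
#'
#' The TSV has columns `template_id`, `pdb` (file name relative to the TSV),
#' `prd_chain`, `peptide_chain`, `peptide_seq`, `multimer`.
#'
#' @param meta_path Path to the metadata TSV.
#' @return List with `templates` (list of `template_complex`) and
#'   `peptide_seqs` (named character vector).
#' @export
read_templates <- function(meta_path) {
  meta <- read_tsv(meta_path)
  dir <- dirname(meta_path)
  templates <- lapply(seq_len(nrow(meta)), function(i) {
    st <- parse_pdb(file.path(dir, meta$pdb[i]))
    template_complex(st, meta$template_id[i], meta$prd_chain[i],
                     meta$peptide_chain[i],
                     multimer_flag = isTRUE(as.logical(meta$multimer[i])))
  })
  list(templates = templates,
       peptide_seqs = setNames(meta$peptide_seq, meta$template_id))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c(if (inherits(e, "dmi_missing_input")) "dmi_missing_input",
                "dmi_stage_error", "error")))
  })
}

#' Run the full prediction pipeline
#'
#' Executes consensus and template-peptide scanning, disorder and
#' conservation feature extraction, the structural interface filters,
#' clue-LR training on the TP/TN sets, per-pair aggregation, NS combination
#' and strong-prediction flagging.  Writes `predictions.tsv` and `run.log`
#' under the configured output directory.
#'
#' @param config A [run_config()] or the path to a flat key-value file.
#' @return The prediction data.frame, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("# pipeline run, %s", format(Sys.time())),
                 vapply(c("distance_cutoff", "asa_threshold", "coverage_min",
                          "top_fraction", "disorder_cutoff", "consv_window",
                          "strong_threshold", "alpha", "lr_cap", "policy",
                          "seed"),
                        function(k) sprintf("config %s = %s", k,
                                            as.character(config[[k]])),
                        character(1)))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  proteome <- stage("read_proteome", read_fasta(config$proteome))
  classes <- stage("read_elm_classes", read_elm_classes(config$elm_classes))
  domains <- stage("read_domains",
                   read_domain_annotations(config$domains, proteome))
  disorder <- stage("read_disorder", read_disorder(config$disorder))
  pairs <- stage("read_pairs",
                 read_pair_set(config$tp_pairs, config$tn_pairs))
  ns <- stage("read_ns", read_ns_table(config$ns))
  tinfo <- stage("read_templates", read_templates(config$templates_meta))
  alns <- stage("read_struct_alignments",
                read_struct_alignments(config$struct_alignments))
  say("inputs: %d proteins, %d classes, %d domain annotations, %d templates",
      nrow(proteome), nrow(classes), nrow(domains),
      length(tinfo$templates))

  consv_flags <- stage("conservation", {
    out <- list()
    for (id in proteome$protein_id) {
      msa_path <- file.path(config$msa_dir, paste0(id, ".fasta"))
      if (!file.exists(msa_path)) {
        stop(errorCondition(sprintf("input file not found: %s", msa_path),
                            class = c("dmi_missing_input", "error")))
      }
      sc <- column_conservation(read_msa(msa_path), id)
      out[[id]] <- local_conservation(sc, config$consv_window)
    }
    out
  })

  motif_clues <- function(pid, start, end) {
    d <- motif_disorder(disorder[[pid]], start, end,
                        cutoff = config$disorder_cutoff)
    list(diso = d$disordered,
         consv = motif_conserved(consv_flags[[pid]], start, end))
  }

  prd_matches <- stage("scan_elm", {
    rows <- list()
    for (ci in seq_len(nrow(classes))) {
      carriers <- domains$protein_id[domains$family_id ==
                                       classes$family_id[ci]]
      if (length(carriers) == 0) next
      for (pi in seq_len(nrow(proteome))) {
        hits <- match_consensus(proteome[pi, ], classes[ci, ])
        for (h in seq_len(nrow(hits))) {
          cl <- motif_clues(hits$protein_id[h], hits$start[h], hits$end[h])
          partners <- setdiff(carriers, hits$protein_id[h])
          if (length(partners) == 0) next
          rows[[length(rows) + 1]] <- data.frame(
            protein_a = partners, protein_b = hits$protein_id[h],
            method = "prd_motif", source = classes$class_id[ci],
            class = classes$class_id[ci], psd = NA_character_,
            sim = NA_character_, diso = cl$diso, consv = cl$consv,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  say("PRD/motif candidate interfaces: %d",
      if (is.null(prd_matches)) 0L else nrow(prd_matches))

  struct_matches <- stage("struct_map", {
    rows <- list()
    templates <- filter_templates(tinfo$templates)
    for (tpl in templates) {
      interf <- interfacial_residues(tpl, config$distance_cutoff)
      pep <- tinfo$peptide_seqs[tpl$template_id]
      cand <- scan_template_motif(proteome, pep,
                                  top_fraction = config$top_fraction,
                                  template_id = tpl$template_id)
      cand <- cand[!is.na(cand$sim_bin), , drop = FALSE]
      t_alns <- Filter(function(a) a$template_id == tpl$template_id, alns)
      for (a in t_alns) {
        bin <- assign_psd_bin(a$psd)
        if (is.na(bin)) next
        model_path <- file.path(config$model_dir,
                                paste0(a$protein_id, "_", a$template_id,
                                       ".pdb"))
        surf <- accessible_surface(parse_pdb(model_path),
                                   threshold = config$asa_threshold)
        cov <- interface_coverage(a, interf, surf, config$coverage_min)
        if (!cov$pass) next
        for (h in seq_len(nrow(cand))) {
          if (cand$protein_id[h] == a$protein_id) next
          cl <- motif_clues(cand$protein_id[h], cand$start[h], cand$end[h])
          rows[[length(rows) + 1]] <- data.frame(
            protein_a = a$protein_id, protein_b = cand$protein_id[h],
            method = "struct", source = tpl$template_id,
            class = NA_character_, psd = bin, sim = cand$sim_bin[h],
            diso = cl$diso, consv = cl$consv, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  say("Struct candidate interfaces: %d",
      if (is.null(struct_matches)) 0L else nrow(struct_matches))

  matches <- rbind(prd_matches, struct_matches)
  if (is.null(matches) || nrow(matches) == 0) {
    stop(errorCondition("pipeline stage 'scan' failed: no candidate ",
                        class = c("dmi_stage_error", "error")))
  }

  fit <- stage("train", dmi_nb(matches, pairs, alpha = config$alpha,
                               lr_cap = config$lr_cap))
  all_pairs <- rbind(pairs$positives, pairs$negatives)
  pred <- stage("predict",
                predict(fit, matches, ns_table = ns, policy = config$policy,
                        threshold = config$strong_threshold,
                        extra_pairs = all_pairs))
  say("predictions: %d pairs, %d strong (LR > %g)", nrow(pred),
      sum(pred$strong), config$strong_threshold)

  pred_path <- file.path(config$out_dir, "predictions.tsv")
  write_predictions(pred, pred_path)
  write_lr_table(fit$table, file.path(config$out_dir, "lr_table.tsv"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(pred)
}
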