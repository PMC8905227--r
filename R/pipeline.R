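# End-to-end orchestration: classify -> filter -> coding -> DE ->
# homology -> network -> cluster/enrich over either simulated or on-disk
# inputs, with a run manifest recording every threshold, input checksum
# and per-stage record count. Amplicon edit scanning and the phenotype
# statistics are independent entry points (classify_reads/summarize_editing
# and the pheno_stats functions) since they consume unrelated inputs.

#' Default pipeline configuration
#'
#' @param simulate generate inputs with the synthetic generator.
#' @param seed master seed for the run.
#' @param sim_config configuration for the generator (when simulating).
#' @param inputs named list of file paths when not simulating: genome,
#'   reference_gtf, assembled_gtf, counts, design, est_bed, gene_order,
#'   annotation.
#' @param filter [filter_params()] settings.
#' @param de list(lfc_threshold, alpha, fdr).
#' @param homology list(min_identity, min_coverage, flank_k, min_shared).
#' @param network list(beta, edge_cutoff, auto_beta, r2_target, max_nodes).
#' @param cluster list(k, n_init, enrich_alpha).
#' @export
pipeline_config <- function(simulate = TRUE, seed = 1L,
                            sim_config = NULL, inputs = NULL,
                            filter = list(), de = list(), homology = list(),
                            network = list(), cluster = list()) {
  merge_opts <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    simulate = isTRUE(simulate),
    seed = as.integer(seed),
    sim_config = sim_config,
    inputs = inputs,
    filter = merge_opts(list(min_length = 200L, min_fpkm = 0.5,
                             min_gene_distance = 500L, allowed_codes = "u",
                             require_est_support = TRUE), filter),
    de = merge_opts(list(lfc_threshold = 2, alpha = 0.05, fdr = FALSE), de),
    homology = merge_opts(list(min_identity = 0.85, min_coverage = 0.8,
                               flank_k = 5L, min_shared = 2L), homology),
    network = merge_opts(list(beta = 8, edge_cutoff = 0.9,
                              auto_beta = FALSE, r2_target = 0.9,
                              max_nodes = 200L), network),
    cluster = merge_opts(list(k = 10L, n_init = 10L, enrich_alpha = 0.01),
                         cluster)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full lncRNA analysis pipeline
#'
#' Stage order: class-code assignment, filter cascade, coding-potential
#' screen (hexamer model trained on reference mRNAs vs the positional
#' candidates, plus protein-database evidence), per-contrast differential
#' expression (each post-infestation timepoint vs 0 h within genotype),
#' subgenome homolog pairing with synteny filter and expression bias,
#' co-expression network with hub detection, and k-means clustering with
#' enrichment-based function transfer. Outputs are written as
#' deterministically sorted TSVs plus a JSON manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; NULL returns results without writing.
#' @param force overwrite an existing output directory.
#' @return list with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         force = FALSE) {
  stopifnot(methods::is(config, "pipeline_config"))
  if (!is.null(out_dir) && dir.exists(out_dir) && !force &&
      length(list.files(out_dir)) > 0) {
    stop("output directory exists; use force = TRUE to overwrite")
  }
  manifest <- list(tool = "lincforge",
                   version = as.character(packageVersion("lincforge")),
                   seed = config$seed,
                   parameters = config[c("filter", "de", "homology",
                                         "network", "cluster")],
                   stages = list())
  note_stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out)
  }

  # --- inputs --------------------------------------------------------------
  if (config$simulate) {
    sc <- config$sim_config %||% sim_config(seed = config$seed)
    sim <- simulate_genome(sc)
    cnt <- simulate_counts(sim, sc)
    annotation <- simulate_annotation(cnt$truth, sc)
    genome <- sim$genome
    reference <- sim$reference
    assembled <- sim$assembled
    tx_seqs <- sim$transcript_seqs
    mrna_seqs <- sim$mrna_seqs
    est <- sim$est
    gene_order <- sim$gene_order
    counts <- cnt$expr
    truth <- cnt$truth
    protein_db <- sim$protein_db
    input_checksums <- list()
  } else {
    ins <- config$inputs
    need <- c("genome", "reference_gtf", "assembled_gtf", "counts",
              "design", "est_bed", "gene_order")
    missing_in <- need[!vapply(need, function(k) {
      !is.null(ins[[k]]) && file.exists(ins[[k]])
    }, logical(1))]
    if (length(missing_in) > 0) {
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
    }
    genome <- read_fasta(ins$genome)
    reference <- read_gtf(ins$reference_gtf)
    assembled <- read_gtf(ins$assembled_gtf)
    est <- read_bed3(ins$est_bed)
    gene_order <- read_tsv(ins$gene_order)
    cm <- read_tsv(ins$counts)
    rownames(cm) <- cm$feature_id
    design <- read_tsv(ins$design)
    values <- as.matrix(cm[, setdiff(names(cm), "feature_id"), drop = FALSE])
    asm_ids <- unique(assembled$transcript_id)
    tx_seqs <- setNames(vapply(asm_ids, function(tid) {
      spliced_sequence(genome, assembled[assembled$transcript_id == tid, ])
    }, character(1)), asm_ids)
    ref_ids <- unique(reference$transcript_id)
    mrna_seqs <- setNames(vapply(ref_ids, function(tid) {
      spliced_sequence(genome, reference[reference$transcript_id == tid, ])
    }, character(1)), ref_ids)
    lens <- setNames(nchar(c(tx_seqs, mrna_seqs)),
                     c(names(tx_seqs), names(mrna_seqs)))
    counts <- expression_matrix(values, design = design,
                                feature_length = lens[rownames(values)],
                                type = "counts")
    annotation <- if (!is.null(ins$annotation) && file.exists(ins$annotation))
      read_tsv(ins$annotation) else NULL
    protein_db <- if (!is.null(ins$protein_db) && file.exists(ins$protein_db))
      setNames(as.character(Biostrings::readAAStringSet(ins$protein_db)),
               names(Biostrings::readAAStringSet(ins$protein_db))) else
      character(0)
    truth <- NULL
    input_checksums <- lapply(ins, function(f) unname(tools::md5sum(f)))
  }
  manifest$input_checksums <- input_checksums
  design <- counts$design

  # --- classify + filter ---------------------------------------------------
  assigned <- assign_class_codes(assembled, reference)
  note_stage("classify", length(unique(assembled$transcript_id)),
             nrow(assigned))
  fpkm <- counts_to_fpkm(counts)
  fpkm_asm <- fpkm$values[intersect(rownames(fpkm$values),
                                    assigned$transcript_id), , drop = FALSE]
  fp <- do.call(filter_params, config$filter)
  filt <- filter_candidates(assigned, assembled,
                            expression_matrix(fpkm_asm, type = "fpkm"),
                            fp, est)
  note_stage("filter", nrow(assigned), length(filt$candidates))

  # --- coding screen -------------------------------------------------------
  cand_seqs <- tx_seqs[filt$candidates]
  model <- train_hexamer_model(unname(mrna_seqs), unname(cand_seqs))
  scores <- do.call(rbind, lapply(filt$candidates, function(id) {
    cbind(transcript_id = id, score_coding(cand_seqs[[id]], model))
  }))
  coding_flag <- scores$transcript_id[scores$label == "coding"]
  if (length(protein_db) > 0) {
    for (id in filt$candidates) {
      orfs <- find_orfs(cand_seqs[[id]], min_peptide_aa = 20)
      if (nrow(orfs) == 0) next
      hits <- protein_hits(setNames(orfs$peptide[1], "longest"),
                           protein_db, min_score = 50)
      if (any(hits$hit)) coding_flag <- union(coding_flag, id)
    }
  }
  lnc_final <- sort(setdiff(filt$candidates, coding_flag))
  note_stage("coding", length(filt$candidates), length(lnc_final))

  # --- differential expression --------------------------------------------
  contrasts <- list()
  if (!is.null(design$timepoint_h) && !is.null(design$genotype)) {
    for (g in unique(design$genotype)) {
      tps <- sort(unique(design$timepoint_h[design$genotype == g]))
      tps <- tps[tps > 0]
      for (tp in tps) {
        sel <- design$genotype == g & design$timepoint_h %in% c(0, tp)
        if (sum(design$timepoint_h[sel] == 0) < 2 ||
            sum(design$timepoint_h[sel] == tp) < 2) next
        nm <- sprintf("%s_%dh", g, tp)
        grp <- factor(ifelse(design$timepoint_h[sel] == 0, "control",
                             "infested"), levels = c("control", "infested"))
        contrasts[[nm]] <- call_de(counts$values[, sel, drop = FALSE], grp,
                                   lfc_threshold = config$de$lfc_threshold,
                                   alpha = config$de$alpha,
                                   fdr = config$de$fdr)
      }
    }
  }
  mrna_ids <- names(mrna_seqs)
  del_summary <- if (length(contrasts) > 0) {
    summarize_del(contrasts, list(lncRNA = lnc_final, mRNA = mrna_ids))
  } else {
    NULL
  }
  note_stage("de", nrow(counts$values), length(contrasts))

  # --- subgenome homology --------------------------------------------------
  lnc_chrom <- vapply(lnc_final, function(id) {
    assembled$chrom[assembled$transcript_id == id][1]
  }, character(1))
  at_ids <- lnc_final[substr(lnc_chrom, 1, 1) == "A"]
  dt_ids <- lnc_final[substr(lnc_chrom, 1, 1) == "D"]
  pairs <- reciprocal_best_pairs(tx_seqs[at_ids], tx_seqs[dt_ids],
                                 min_identity = config$homology$min_identity,
                                 min_coverage = config$homology$min_coverage)
  if (nrow(pairs) > 0 && !is.null(gene_order)) {
    at_order <- gene_order[substr(gene_order$chrom, 1, 1) == "A", ]
    dt_order <- gene_order[substr(gene_order$chrom, 1, 1) == "D", ]
    pairs <- synteny_filter(pairs, at_order, dt_order,
                            flank_k = config$homology$flank_k,
                            min_shared = config$homology$min_shared)
  }
  bias <- NULL
  if (nrow(pairs) > 0 && length(contrasts) > 0) {
    last <- contrasts[[length(contrasts)]]
    bias <- tryCatch(pair_expression_bias(pairs, last),
                     error = function(e) NULL)
  }
  note_stage("homology", length(at_ids) + length(dt_ids), nrow(pairs))

  # --- co-expression network ----------------------------------------------
  sig_mrna <- character(0)
  if (length(contrasts) > 0) {
    sig_mrna <- sort(unique(unlist(lapply(contrasts, function(r) {
      intersect(r$feature_id[r$significant], mrna_ids)
    }))))
  }
  net_ids <- unique(c(lnc_final, sig_mrna))
  net_fpkm <- fpkm$values[intersect(net_ids, rownames(fpkm$values)), ,
                          drop = FALSE]
  v <- apply(net_fpkm, 1, var)
  net_fpkm <- net_fpkm[v > 0, , drop = FALSE]
  if (nrow(net_fpkm) > config$network$max_nodes) {
    keep <- order(apply(net_fpkm, 1, var),
                  decreasing = TRUE)[seq_len(config$network$max_nodes)]
    net_fpkm <- net_fpkm[sort(keep), , drop = FALSE]
  }
  kind <- setNames(ifelse(rownames(net_fpkm) %in% lnc_final, "lncRNA",
                          "PCG"), rownames(net_fpkm))
  beta <- config$network$beta
  beta_fit <- NULL
  if (config$network$auto_beta && ncol(net_fpkm) >= 8 &&
      nrow(net_fpkm) >= 10) {
    st <- pick_soft_threshold(net_fpkm, r2_target = config$network$r2_target)
    beta <- st$beta
    beta_fit <- st$fit
  }
  network <- if (nrow(net_fpkm) >= 2) {
    build_network(net_fpkm, beta = beta,
                  edge_cutoff = config$network$edge_cutoff, kind = kind)
  } else {
    NULL
  }
  hubs <- if (!is.null(network)) find_hubs(network, top_n = 3) else NULL
  note_stage("network", nrow(net_fpkm),
             if (is.null(network)) 0L else nrow(network$edges))

  # --- clustering + enrichment + function transfer -------------------------
  clus_ids <- unique(c(lnc_final, sig_mrna))
  clus_m <- fpkm$values[intersect(clus_ids, rownames(fpkm$values)), ,
                        drop = FALSE]
  clus_m <- clus_m[apply(clus_m, 1, var) > 0, , drop = FALSE]
  clustering <- NULL
  transfer <- NULL
  if (nrow(clus_m) >= config$cluster$k) {
    clustering <- kmeans_profiles(clus_m, k = config$cluster$k,
                                  seed = config$seed,
                                  n_init = config$cluster$n_init)
    if (!is.null(annotation)) {
      kind_all <- setNames(ifelse(rownames(clus_m) %in% lnc_final,
                                  "lncRNA", "PCG"), rownames(clus_m))
      transfer <- transfer_function(clustering$assignments, kind_all,
                                    annotation,
                                    alpha = config$cluster$enrich_alpha)
    }
  }
  note_stage("cluster", nrow(clus_m),
             if (is.null(clustering)) 0L else config$cluster$k)

  res <- list(assigned = assigned, filter = filt, coding_scores = scores,
              lnc_final = lnc_final, contrasts = contrasts,
              del_summary = del_summary, pairs = pairs, bias = bias,
              network = network, hubs = hubs, beta_fit = beta_fit,
              clustering = clustering, transfer = transfer,
              truth = truth, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) write_tsv(df[order(df[[1]]), , drop = FALSE],
                                   file.path(out_dir, f))
    w(assigned, "class_codes.tsv")
    w(filt$ledger, "filter_ledger.tsv")
    w(scores, "coding_scores.tsv")
    writeLines(lnc_final, file.path(out_dir, "lncrna_final.txt"))
    for (nm in names(contrasts)) {
      w(contrasts[[nm]], sprintf("de_%s.tsv", nm))
    }
    if (nrow(pairs) > 0) w(pairs, "homolog_pairs.tsv")
    if (!is.null(network)) {
      write_edge_list(network, file.path(out_dir, "network_edges.tsv"))
    }
    if (!is.null(hubs) && nrow(hubs) > 0) w(hubs, "hubs.tsv")
    if (!is.null(clustering)) w(clustering$assignments, "clusters.tsv")
    if (!is.null(transfer) && nrow(transfer$associations) > 0) {
      w(transfer$associations, "lnc_function_associations.tsv")
    }
    manifest$config_hash <- digest_config(config)
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}
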