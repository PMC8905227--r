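# Synthetic two-subgenome fixture generator.
#
# Emulates an allotetraploid (At/Dt) cotton-like genome carrying
# protein-coding genes and planted intergenic ("u"), intronic ("i") and
# antisense ("x") non-coding transcripts, per-filter decoys, syntenic and
# shuffled-block homolog pairs, a 2-genotype x 5-timepoint expression design
# with planted differential expression, and CRISPR amplicon read sets with
# planted editing outcomes. Every generated feature is recorded in a truth
# table so downstream stages can be scored against known labels.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' study conditions emulated throughout the package: a two-subgenome genome,
#' a resistant (HR) / susceptible (ZS) genotype pair sampled at 0, 4, 12, 24
#' and 48 h after infestation with three replicates, negative-binomial count
#' noise, and planted fold changes at the magnitude the differential
#' expression caller is expected to recover.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_chromosomes_per_subgenome chromosomes per subgenome (named
#'   A01..Ann and D01..Dnn).
#' @param chromosome_length length of every chromosome in bp.
#' @param n_genes total protein-coding genes across both subgenomes
#'   (includes synteny anchor genes).
#' @param n_lnc_u,n_lnc_i,n_lnc_x planted intergenic / intronic / antisense
#'   non-coding transcripts. `n_lnc_u` must cover the homolog-pair members:
#'   `n_lnc_u >= 2 * (n_homolog_pairs + n_shuffled_pairs)`.
#' @param n_homolog_pairs At/Dt lncRNA pairs planted in syntenic blocks
#'   (flanking anchor-gene order preserved across subgenomes).
#' @param n_shuffled_pairs sequence-homologous pairs whose Dt member sits in
#'   a non-syntenic neighbourhood (synteny-filter decoys).
#' @param n_decoys_per_rule intergenic decoys planted per filter rule
#'   (short, near-gene, coding-ORF, low-expression, no-EST-support).
#' @param n_mrna_copies assembled transcripts that are exact copies of
#'   reference mRNAs (class `overlapping_other` decoys).
#' @param design data.frame with columns genotype, timepoint_h, replicate;
#'   one row per RNA-seq sample.
#' @param de_fraction fraction of free (non-pair) intergenic lncRNAs planted
#'   as differentially expressed; the same fraction of mRNAs divided by
#'   `mrna_de_shrink` is planted DE so the lncRNA DE ratio exceeds the mRNA
#'   ratio, as observed in infestation data.
#' @param de_log2fc planted |log2 fold change| for DE features (applied at
#'   every post-infestation timepoint relative to 0 h).
#' @param mrna_de_shrink divisor making the mRNA DE fraction smaller than
#'   the lncRNA DE fraction.
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2); 0 degenerates to Poisson.
#' @param read_error_rate per-base substitution error rate for amplicon
#'   reads (no indel errors are simulated).
#' @param lnc_gc,coding_gc target GC fractions for non-coding and coding
#'   sequence generation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes_per_subgenome = 2L,
                       chromosome_length = 400000L,
                       n_genes = 120L,
                       n_lnc_u = 60L,
                       n_lnc_i = 15L,
                       n_lnc_x = 15L,
                       n_homolog_pairs = 6L,
                       n_shuffled_pairs = 3L,
                       n_decoys_per_rule = 10L,
                       n_mrna_copies = 60L,
                       design = default_design(),
                       de_fraction = 0.3,
                       de_log2fc = 3,
                       mrna_de_shrink = 3,
                       dispersion = 0.1,
                       read_error_rate = 0.001,
                       lnc_gc = 0.36,
                       coding_gc = 0.44) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes_per_subgenome = as.integer(n_chromosomes_per_subgenome),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    n_lnc_u = as.integer(n_lnc_u),
    n_lnc_i = as.integer(n_lnc_i),
    n_lnc_x = as.integer(n_lnc_x),
    n_homolog_pairs = as.integer(n_homolog_pairs),
    n_shuffled_pairs = as.integer(n_shuffled_pairs),
    n_decoys_per_rule = as.integer(n_decoys_per_rule),
    n_mrna_copies = as.integer(n_mrna_copies),
    design = design,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc,
    mrna_de_shrink = mrna_de_shrink,
    dispersion = dispersion,
    read_error_rate = read_error_rate,
    lnc_gc = lnc_gc,
    coding_gc = coding_gc
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default RNA-seq sample design
#'
#' Two genotypes (HR resistant, ZS susceptible) x five timepoints after
#' infestation (0, 4, 12, 24, 48 h) x `n_replicates`.
#'
#' @param n_replicates replicates per genotype/timepoint combination.
#' @export
default_design <- function(n_replicates = 3L) {
  d <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint_h = c(0L, 4L, 12L, 24L, 48L),
                   genotype = c("HR", "ZS"),
                   stringsAsFactors = FALSE)
  d <- d[, c("genotype", "timepoint_h", "replicate")]
  d$sample_id <- sprintf("%s_%02dh_r%d", d$genotype, d$timepoint_h,
                         d$replicate)
  d
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$dispersion >= 0,
            cfg$read_error_rate >= 0, cfg$read_error_rate < 1,
            cfg$n_chromosomes_per_subgenome >= 1,
            nrow(cfg$design) >= 1)
  need <- 2L * (cfg$n_homolog_pairs + cfg$n_shuffled_pairs)
  if (cfg$n_lnc_u < need) {
    stop("n_lnc_u (", cfg$n_lnc_u, ") must cover homolog pair members (",
         need, ")")
  }
  anchors <- 8L * cfg$n_homolog_pairs + 4L * cfg$n_shuffled_pairs
  if (cfg$n_genes < anchors + 2L * cfg$n_chromosomes_per_subgenome) {
    stop("n_genes too small to provide synteny anchors (need > ", anchors, ")")
  }
  invisible(cfg)
}

# Codon sampling weights used for coding sequence: independent base
# composition per codon position, stop codons removed. The resulting
# in-frame hexamer spectrum (and absence of in-frame stops) is the signal
# the hexamer classifier learns.
coding_codon_table <- function(gc = 0.44) {
  p <- c(A = (1 - gc) / 2 + 0.03, C = gc / 2 - 0.02,
         G = gc / 2 + 0.04, T = (1 - gc) / 2 - 0.05)
  p <- p / sum(p)
  codons <- as.vector(outer(outer(names(p), names(p), paste0), names(p),
                            paste0))
  w <- as.vector(outer(outer(p, p), p))
  keep <- !(codons %in% STOP_CODONS)
  list(codons = codons[keep], weights = w[keep] / sum(w[keep]))
}

make_cds <- function(n_aa, codon_tab) {
  body <- sample(codon_tab$codons, n_aa, replace = TRUE,
                 prob = codon_tab$weights)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# Split a transcript of length len into k exon chunk lengths (each >= 60).
split_exons <- function(len, k) {
  if (k == 1) return(len)
  repeat {
    cuts <- sort(sample(seq(60, len - 60), k - 1))
    w <- diff(c(0, cuts, len))
    if (all(w >= 60)) return(w)
  }
}

round_robin <- function(n_items, n_groups) {
  ((seq_len(n_items) - 1L) %% n_groups) + 1L
}

#' Generate a synthetic two-subgenome genome with planted lncRNAs
#'
#' Builds chromosome sequences, a reference gene annotation, an
#' assembled-transcript set containing planted lncRNAs plus decoys designed
#' to fail each individual filter rule, EST support intervals, a protein
#' database, per-chromosome gene-order tables for the synteny filter, and a
#' truth table recording every planted label.
#'
#' @param config a [sim_config()].
#' @return list of class `cotton_sim` with elements `genome` (named
#'   character vector of chromosome sequences), `reference` and `assembled`
#'   (exon tables, 0-based half-open), `transcript_seqs` and `mrna_seqs`
#'   (spliced sequences), `truth` (truth table), `est` (BED-like intervals),
#'   `protein_db` (named amino-acid sequences), `gene_order` (per-feature
#'   chromosome order table with anchor ids), and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n_chr <- cfg$n_chromosomes_per_subgenome
  chroms_a <- sprintf("A%02d", seq_len(n_chr))
  chroms_d <- sprintf("D%02d", seq_len(n_chr))
  codon_tab <- coding_codon_table(cfg$coding_gc)

  # --- feature bookkeeping -------------------------------------------------
  nh <- cfg$n_homolog_pairs
  ns <- cfg$n_shuffled_pairs
  n_pair_members <- 2L * (nh + ns)
  n_free_u <- cfg$n_lnc_u - n_pair_members
  n_anchor_placements <- 8L * nh + 4L * ns
  n_free_genes <- cfg$n_genes - n_anchor_placements

  gene_ctr <- 0L
  new_gene_id <- function(anchor) {
    gene_ctr <<- gene_ctr + 1L
    sprintf("gene%04d", gene_ctr)
  }

  # Plan: per chromosome an ordered list of placement units.
  plan <- setNames(vector("list", 2L * n_chr), c(chroms_a, chroms_d))
  add_unit <- function(chrom, unit) {
    plan[[chrom]][[length(plan[[chrom]]) + 1L]] <<- unit
  }

  # Syntenic blocks: two anchors each side of the pair lncRNA; identical
  # anchor base-ids and order on the A and D chromosome of the same index.
  for (b in seq_len(nh)) {
    ci <- ((b - 1L) %% n_chr) + 1L
    anchor_ids <- sprintf("anch%03d", (b - 1L) * 4L + 1:4)
    for (sg in c("A", "D")) {
      chrom <- sprintf("%s%02d", sg, ci)
      lnc_id <- sprintf("lnc_pair%02d_%st", b, tolower(sg))
      add_unit(chrom, list(type = "gene", anchor = anchor_ids[1]))
      add_unit(chrom, list(type = "gene", anchor = anchor_ids[2]))
      add_unit(chrom, list(type = "lnc_u", id = lnc_id,
                           pair = sprintf("pair%02d", b), pair_kind = "syntenic"))
      add_unit(chrom, list(type = "gene", anchor = anchor_ids[3]))
      add_unit(chrom, list(type = "gene", anchor = anchor_ids[4]))
    }
  }
  # Shuffled pairs: anchored block on the A side only; the D member is
  # dropped between free genes so its flanking anchors have no A homologs.
  for (b in seq_len(ns)) {
    ci <- ((b - 1L) %% n_chr) + 1L
    anchor_ids <- sprintf("shan%03d", (b - 1L) * 4L + 1:4)
    chrom <- sprintf("A%02d", ci)
    add_unit(chrom, list(type = "gene", anchor = anchor_ids[1]))
    add_unit(chrom, list(type = "gene", anchor = anchor_ids[2]))
    add_unit(chrom, list(type = "lnc_u", id = sprintf("lnc_shuf%02d_at", b),
                         pair = sprintf("shuf%02d", b), pair_kind = "shuffled"))
    add_unit(chrom, list(type = "gene", anchor = anchor_ids[3]))
    add_unit(chrom, list(type = "gene", anchor = anchor_ids[4]))
    add_unit(sprintf("D%02d", ci),
             list(type = "lnc_u", id = sprintf("lnc_shuf%02d_dt", b),
                  pair = sprintf("shuf%02d", b), pair_kind = "shuffled"))
  }

  all_chroms <- c(chroms_a, chroms_d)
  # Free genes, free u lncRNAs and decoys round-robin across chromosomes.
  for (i in seq_len(n_free_genes)) {
    add_unit(all_chroms[round_robin(n_free_genes, 2L * n_chr)[i]],
             list(type = "gene", anchor = sprintf("free%03d", i)))
  }
  for (i in seq_len(n_free_u)) {
    add_unit(all_chroms[round_robin(n_free_u, 2L * n_chr)[i]],
             list(type = "lnc_u", id = sprintf("lnc_u%03d", i),
                  pair = NA_character_, pair_kind = NA_character_))
  }
  # near_gene decoys are positioned after placement, beside chosen genes
  decoy_rules <- c("short", "coding", "low_fpkm", "no_est")
  for (r in decoy_rules) {
    for (i in seq_len(cfg$n_decoys_per_rule)) {
      add_unit(all_chroms[round_robin(cfg$n_decoys_per_rule, 2L * n_chr)[i]],
               list(type = paste0("decoy_", r),
                    id = sprintf("decoy_%s%03d", r, i)))
    }
  }
  # Shuffle placement order within each chromosome, keeping block units
  # contiguous: units were appended block-first, so permute at block level.
  # Simpler: leave block units first and interleave free units after them
  # in randomized order.
  for (ch in names(plan)) {
    units <- plan[[ch]]
    is_block <- vapply(units, function(u) {
      (!is.null(u$anchor) && grepl("^(anch|shan)", u$anchor)) ||
        (!is.null(u$pair) && !is.na(u$pair))
    }, logical(1))
    free_units <- units[!is_block]
    block_units <- units[is_block]
    if (length(free_units) > 1) free_units <- sample(free_units)
    # Interleave: put roughly half of the free units before the blocks.
    n_pre <- floor(length(free_units) / 2)
    plan[[ch]] <- c(free_units[seq_len(n_pre)], block_units,
                    free_units[setdiff(seq_along(free_units),
                                       seq_len(n_pre))])
  }

  # --- placement -----------------------------------------------------------
  ref_exons <- list()
  asm_exons <- list()
  truth <- list()
  seq_patches <- list()   # genomic intervals to overwrite with feature seq
  tx_seqs <- character(0) # assembled transcript spliced sequences
  mrna_seqs <- character(0)
  gene_meta <- list()     # per gene: chrom, start, end, strand, introns, exons
  order_rows <- list()

  pair_seq_cache <- list() # At member sequence reused (mutated) for Dt member

  for (ch in names(plan)) {
    cursor <- 1000L
    sg <- substr(ch, 1, 1)
    for (u in plan[[ch]]) {
      gap_after <- sample(1500:2500, 1)
      if (u$type == "gene") {
        gid <- new_gene_id()
        n_aa <- sample(80:200, 1)
        cds <- make_cds(n_aa, codon_tab)
        k <- sample(2:4, 1)
        exon_w <- split_exons(nchar(cds), k)
        intron_w <- if (k > 1) sample(450:900, k - 1, replace = TRUE)
                    else integer(0)
        strand <- sample(c("+", "-"), 1)
        span <- sum(exon_w) + sum(intron_w)
        starts <- cursor + cumsum(c(0L, head(exon_w, -1) + intron_w))
        ends <- starts + exon_w
        if (max(ends) > cfg$chromosome_length - 1000L) {
          stop("chromosome_length (", cfg$chromosome_length,
               ") too short to host requested features on ", ch,
               "; increase chromosome_length or reduce feature counts")
        }
        tid <- paste0(gid, ".1")
        ref_exons[[length(ref_exons) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, chrom = ch, strand = strand,
          start = starts, end = ends, stringsAsFactors = FALSE)
        # write CDS into the genome (reverse-complemented for minus strand)
        genomic_seq <- if (strand == "+") cds else reverse_complement(cds)
        offs <- cumsum(c(0L, exon_w))
        for (e in seq_len(k)) {
          seq_patches[[length(seq_patches) + 1L]] <- list(
            chrom = ch, start = starts[e],
            seq = substr(genomic_seq, offs[e] + 1L, offs[e + 1L]))
        }
        mrna_seqs[tid] <- cds
        gene_meta[[gid]] <- list(gene_id = gid, chrom = ch, strand = strand,
                                 start = cursor, end = cursor + span,
                                 exon_starts = starts, exon_ends = ends,
                                 anchor = u$anchor)
        order_rows[[length(order_rows) + 1L]] <- data.frame(
          chrom = ch, id = gid, kind = "gene", anchor_id = u$anchor,
          start = cursor, stringsAsFactors = FALSE)
        cursor <- cursor + span + gap_after
      } else {
        # intergenic single- or two-exon transcript units
        rule <- sub("^decoy_", "", u$type)
        is_decoy <- grepl("^decoy_", u$type)
        len <- if (is_decoy && rule == "short") sample(120:180, 1)
               else sample(250:700, 1)
        id <- u$id
        if (!is.null(u$pair) && !is.na(u$pair) && grepl("_dt$", id)) {
          # Dt pair member: mutate the cached At sequence (substitutions at
          # ~5% of positions) so identity stays well above the RBH default.
          at_seq <- pair_seq_cache[[u$pair]]
          s <- strsplit(at_seq, "")[[1]]
          nmut <- max(1L, round(0.05 * length(s)))
          pos <- sample(length(s), nmut)
          s[pos] <- vapply(s[pos], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
          seqstr <- paste(s, collapse = "")
          len <- nchar(seqstr)
        } else if (is_decoy && rule == "coding") {
          n_aa <- floor((len - 40) / 3)
          cds <- make_cds(n_aa, codon_tab)
          pad <- len - nchar(cds)
          seqstr <- paste0(
            random_dna(1, max(0, floor(pad / 2)), cfg$lnc_gc), cds,
            random_dna(1, max(0, ceiling(pad / 2)), cfg$lnc_gc))
          len <- nchar(seqstr)
        } else {
          seqstr <- random_dna(1, len, cfg$lnc_gc)
        }
        if (!is.null(u$pair) && !is.na(u$pair) && grepl("_at$", id)) {
          pair_seq_cache[[u$pair]] <- seqstr
        }
        strand <- sample(c("+", "-"), 1)
        n_ex <- if (!is_decoy && len >= 400 && runif(1) < 0.35) 2L else 1L
        if (n_ex == 2L) {
          w <- split_exons(len, 2L)
          iw <- sample(120:300, 1)
          starts <- c(cursor, cursor + w[1] + iw)
          ends <- starts + w
        } else {
          starts <- cursor
          ends <- cursor + len
        }
        if (max(ends) > cfg$chromosome_length - 1000L) {
          stop("chromosome_length (", cfg$chromosome_length,
               ") too short to host requested features on ", ch,
               "; increase chromosome_length or reduce feature counts")
        }
        asm_exons[[length(asm_exons) + 1L]] <- data.frame(
          transcript_id = id, gene_id = id, chrom = ch, strand = strand,
          start = starts, end = ends, stringsAsFactors = FALSE)
        genomic_seq <- if (strand == "+") seqstr else reverse_complement(seqstr)
        offs <- cumsum(c(0L, ends - starts))
        for (e in seq_along(starts)) {
          seq_patches[[length(seq_patches) + 1L]] <- list(
            chrom = ch, start = starts[e],
            seq = substr(genomic_seq, offs[e] + 1L, offs[e + 1L]))
        }
        tx_seqs[id] <- seqstr
        truth[[length(truth) + 1L]] <- data.frame(
          feature_id = id,
          kind = if (is_decoy) u$type else "lnc",
          true_class_code = "u",
          true_coding = is_decoy && rule == "coding",
          homolog_partner = NA_character_,
          pair_id = u$pair %||% NA_character_,
          syntenic_truth = if (!is.null(u$pair_kind) &&
                               !is.na(u$pair_kind %||% NA)) {
            identical(u$pair_kind, "syntenic")
          } else NA,
          chrom = ch, subgenome = ifelse(sg == "A", "At", "Dt"),
          length = len, stringsAsFactors = FALSE)
        order_rows[[length(order_rows) + 1L]] <- data.frame(
          chrom = ch, id = id, kind = "lnc", anchor_id = NA_character_,
          start = cursor, stringsAsFactors = FALSE)
        cursor <- max(ends) + gap_after
      }
    }
    if (cursor > cfg$chromosome_length) {
      stop("chromosome_length (", cfg$chromosome_length,
           ") too short to host requested features on ", ch)
    }
  }

  ref_exons <- do.call(rbind, ref_exons)
  truth <- do.call(rbind, truth)

  # --- near-gene decoys: dropped 200-400 bp downstream of a gene span ------
  # The inter-feature gap is always >= 1500 bp, so the first ~1100 bp after a
  # gene span are guaranteed background; a decoy of <= 600 bp placed 200-400
  # bp after the span fails the 500 bp proximity rule and nothing else.
  gene_ids_sorted <- names(gene_meta)
  for (i in seq_len(cfg$n_decoys_per_rule)) {
    g <- gene_meta[[gene_ids_sorted[(i - 1L) * 2L + 1L]]]
    s0 <- g$end + sample(200:400, 1)
    len <- sample(250:600, 1)
    id <- sprintf("decoy_near_gene%03d", i)
    seqstr <- random_dna(1, len, cfg$lnc_gc)
    strand <- sample(c("+", "-"), 1)
    asm_exons[[length(asm_exons) + 1L]] <- data.frame(
      transcript_id = id, gene_id = id, chrom = g$chrom, strand = strand,
      start = s0, end = s0 + len, stringsAsFactors = FALSE)
    seq_patches[[length(seq_patches) + 1L]] <- list(
      chrom = g$chrom, start = s0,
      seq = if (strand == "+") seqstr else reverse_complement(seqstr))
    tx_seqs[id] <- seqstr
    truth <- rbind(truth, data.frame(
      feature_id = id, kind = "decoy_near_gene", true_class_code = "u",
      true_coding = FALSE, homolog_partner = NA_character_,
      pair_id = NA_character_, syntenic_truth = NA, chrom = g$chrom,
      subgenome = ifelse(substr(g$chrom, 1, 1) == "A", "At", "Dt"),
      length = len, stringsAsFactors = FALSE))
  }

  gene_order <- do.call(rbind, order_rows)
  gene_order <- gene_order[order(gene_order$chrom, gene_order$start), ]
  gene_order$rank <- stats::ave(gene_order$start, gene_order$chrom,
                                FUN = function(x) rank(x, ties.method = "first"))

  # --- intronic and antisense lncRNAs (placed inside existing genes) -------
  genes_with_introns <- Filter(function(g) length(g$exon_starts) > 1,
                               gene_meta)
  extra_truth <- list()
  for (i in seq_len(cfg$n_lnc_i)) {
    g <- genes_with_introns[[((i - 1L) %% length(genes_with_introns)) + 1L]]
    # first intron
    istart <- g$exon_ends[1]
    iend <- g$exon_starts[2]
    len <- min(sample(250:350, 1), iend - istart - 40L)
    s0 <- istart + 20L
    id <- sprintf("lnc_i%03d", i)
    seqstr <- random_dna(1, len, cfg$lnc_gc)
    strand <- sample(c("+", "-"), 1)
    asm_exons[[length(asm_exons) + 1L]] <- data.frame(
      transcript_id = id, gene_id = id, chrom = g$chrom, strand = strand,
      start = s0, end = s0 + len, stringsAsFactors = FALSE)
    seq_patches[[length(seq_patches) + 1L]] <- list(
      chrom = g$chrom, start = s0,
      seq = if (strand == "+") seqstr else reverse_complement(seqstr))
    tx_seqs[id] <- seqstr
    extra_truth[[length(extra_truth) + 1L]] <- data.frame(
      feature_id = id, kind = "lnc", true_class_code = "i",
      true_coding = FALSE, homolog_partner = NA_character_,
      pair_id = NA_character_, syntenic_truth = NA, chrom = g$chrom,
      subgenome = ifelse(substr(g$chrom, 1, 1) == "A", "At", "Dt"),
      length = len, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_lnc_x)) {
    g <- gene_meta[[((i * 7L - 1L) %% length(gene_meta)) + 1L]]
    # overlap the first exon on the opposite strand
    ex_s <- g$exon_starts[1]
    ex_e <- g$exon_ends[1]
    len <- sample(250:400, 1)
    s0 <- max(0L, ex_s + sample(10:40, 1))
    id <- sprintf("lnc_x%03d", i)
    strand <- if (g$strand == "+") "-" else "+"
    asm_exons[[length(asm_exons) + 1L]] <- data.frame(
      transcript_id = id, gene_id = id, chrom = g$chrom, strand = strand,
      start = s0, end = s0 + len, stringsAsFactors = FALSE)
    # sequence is whatever the genome holds there (mostly gene sequence);
    # recorded after patches are applied.
    extra_truth[[length(extra_truth) + 1L]] <- data.frame(
      feature_id = id, kind = "lnc", true_class_code = "x",
      true_coding = FALSE, homolog_partner = NA_character_,
      pair_id = NA_character_, syntenic_truth = NA, chrom = g$chrom,
      subgenome = ifelse(substr(g$chrom, 1, 1) == "A", "At", "Dt"),
      length = len, stringsAsFactors = FALSE)
  }
  truth <- rbind(truth, do.call(rbind, extra_truth))

  # --- assembled copies of reference mRNAs ---------------------------------
  ref_tids <- unique(ref_exons$transcript_id)
  n_copy <- min(cfg$n_mrna_copies, length(ref_tids))
  copy_tids <- sort(ref_tids)[seq_len(n_copy)]
  for (tid in copy_tids) {
    ex <- ref_exons[ref_exons$transcript_id == tid, ]
    ex$transcript_id <- paste0("asm_", tid)
    ex$gene_id <- paste0("asm_", tid)
    asm_exons[[length(asm_exons) + 1L]] <- ex
    truth <- rbind(truth, data.frame(
      feature_id = paste0("asm_", tid), kind = "mrna_copy",
      true_class_code = "overlapping", true_coding = TRUE,
      homolog_partner = NA_character_, pair_id = NA_character_,
      syntenic_truth = NA, chrom = ex$chrom[1],
      subgenome = ifelse(substr(ex$chrom[1], 1, 1) == "A", "At", "Dt"),
      length = sum(ex$end - ex$start), stringsAsFactors = FALSE))
    tx_seqs[paste0("asm_", tid)] <- mrna_seqs[[tid]]
  }
  asm_exons <- do.call(rbind, asm_exons)

  # --- assemble chromosome sequences ---------------------------------------
  genome <- setNames(random_dna(length(all_chroms), cfg$chromosome_length,
                                0.40), all_chroms)
  for (p in seq_patches) {
    s <- p$start + 1L
    e <- p$start + nchar(p$seq)
    substr(genome[[p$chrom]], s, e) <- p$seq
  }
  # antisense transcript sequences read from the finished genome
  for (id in truth$feature_id[truth$true_class_code == "x"]) {
    ex <- asm_exons[asm_exons$transcript_id == id, ]
    tx_seqs[id] <- spliced_sequence(genome, ex)
  }

  # --- homolog partner links ----------------------------------------------
  for (pid in unique(stats::na.omit(truth$pair_id))) {
    members <- truth$feature_id[!is.na(truth$pair_id) & truth$pair_id == pid]
    at <- members[grepl("_at$", members)]
    dt <- members[grepl("_dt$", members)]
    truth$homolog_partner[truth$feature_id == at] <- dt
    truth$homolog_partner[truth$feature_id == dt] <- at
  }

  # --- EST support (one interval per supported transcript's first exon) ----
  no_est <- truth$feature_id[truth$kind == "decoy_no_est"]
  supported <- setdiff(unique(asm_exons$transcript_id), no_est)
  est <- do.call(rbind, lapply(supported, function(tid) {
    ex <- asm_exons[asm_exons$transcript_id == tid, ][1, ]
    mid <- floor((ex$start + ex$end) / 2)
    data.frame(chrom = ex$chrom, start = ex$start, end = mid + 10L,
               stringsAsFactors = FALSE)
  }))
  est <- est[order(est$chrom, est$start), ]

  # --- protein database ----------------------------------------------------
  # Translations of half of the coding genes plus the coding decoys' ORFs.
  db_tids <- sort(names(mrna_seqs))[c(TRUE, FALSE)]
  prot <- vapply(db_tids, function(tid) {
    translate_dna(substr(mrna_seqs[[tid]], 1, nchar(mrna_seqs[[tid]]) - 3))
  }, character(1))
  coding_ids <- truth$feature_id[truth$kind == "decoy_coding"]
  for (id in coding_ids) {
    orfs <- find_orfs(tx_seqs[[id]], min_peptide_aa = 20)
    if (nrow(orfs) > 0) {
      prot[paste0("prot_", id)] <- orfs$peptide[1]
    }
  }

  # --- filter-cascade truth flags ------------------------------------------
  truth$true_pass_filter <- truth$true_class_code == "u" &
    truth$length >= 200 &
    truth$kind %in% c("lnc", "decoy_coding")
  truth$true_pass_all <- truth$true_pass_filter & !truth$true_coding
  truth$cluster <- NA_integer_

  rownames(truth) <- NULL
  rownames(asm_exons) <- NULL
  rownames(ref_exons) <- NULL

  structure(list(genome = genome, reference = ref_exons,
                 assembled = asm_exons, transcript_seqs = tx_seqs,
                 mrna_seqs = mrna_seqs, truth = truth, est = est,
                 protein_db = prot, gene_order = gene_order,
                 config = cfg),
            class = "cotton_sim")
}

#' Spliced transcript sequence from a genome
#'
#' Concatenates exon substrings in genomic order and reverse-complements
#' for minus-strand transcripts.
#'
#' @param genome named character vector of chromosome sequences.
#' @param exons exon table rows for one transcript (0-based half-open).
#' @export
spliced_sequence <- function(genome, exons) {
  exons <- exons[order(exons$start), ]
  parts <- vapply(seq_len(nrow(exons)), function(i) {
    substr(genome[[exons$chrom[i]]], exons$start[i] + 1L, exons$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (exons$strand[1] == "-") s <- reverse_complement(s)
  s
}

translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "solve"))
}
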