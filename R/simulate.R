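#' Configuration for the synthetic annotation generator
#'
#' Defines the study conditions the simulator emulates: a small
#' multi-chromosome genome carrying non-overlapping ERV integrations with
#' paired LTRs mutated at a controlled rate-times-age divergence, genes
#' (with overlapping alternative transcripts) placed around the
#' integrations with a configurable antisense bias, interspersed repeats,
#' and assembly gaps of mixed AGP types with known candidacy.  Every
#' planted value is recorded in a ground-truth sidecar, and a fixed seed
#' fully determines the output.
#'
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param n_chromosomes number of chromosomes (default 4).
#' @param chromosome_lengths bp per chromosome (default 3 Mbp each).
#' @param n_ervs number of proviral chains (default 40).
#' @param erv_length_range provirus length range in bp (default 5-10 kb).
#' @param erv_spacing minimum clearance in bp between placed ERVs
#'   (default 0: non-overlapping only).  Setting it to at least twice the
#'   neighborhood window plus the maximal gene extent isolates every
#'   ERV's window from its neighbors' genes.
#' @param ltr_length LTR length in bp (default 400).
#' @param target_ages integration ages (mya) sampled uniformly per ERV
#'   (default `c(0, 2, 12, 25, 100)`, spanning the young / middle / old
#'   divergence classes under the default rate).
#' @param substitution_rate per-lineage neutral rate, fraction/site/mya
#'   (default 0.002).
#' @param n_genes number of genes (default 60), each placed relative to a
#'   random ERV.
#' @param transcripts_per_gene_range alternative-transcript count range
#'   (default 1-3).
#' @param gene_length_range gene span range in bp (default 2-30 kb).
#' @param gene_offset_max maximum |edge offset| of a gene from its ERV in
#'   bp (default 100000, i.e. inside the neighborhood window).
#' @param antisense_bias probability that a gene is placed antisense to
#'   its ERV (default 0.5, the unbiased null).
#' @param n_gaps number of assembly gaps (default 20).
#' @param gap_type_mix sampling weights over AGP gap types
#'   (default fragment 0.6, clone 0.2, contig 0.2).
#' @param gap_length_range gap length range in bp (default 200-5000, so
#'   both sub-1-kb and candidate-sized gaps occur).
#' @param unsized_gap_prob probability a gap is recorded unsized (`U`)
#'   (default 0.1).
#' @param flank_repeat_prob probability a gap gets a planted non-ERV
#'   repeat fragment at one flank (default 0.3).
#' @param repeat_density background repeats per Mbp (default 30).
#' @param putein_error_rate probability a putein carries five or more
#'   undetermined residues (default 0.15).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, n_chromosomes = 4,
                       chromosome_lengths = rep(3e6, n_chromosomes),
                       n_ervs = 40, erv_length_range = c(5000, 10000),
                       erv_spacing = 0, ltr_length = 400,
                       target_ages = c(0, 2, 12, 25, 100),
                       substitution_rate = 0.002, n_genes = 60,
                       transcripts_per_gene_range = c(1, 3),
                       gene_length_range = c(2000, 30000),
                       gene_offset_max = 100000, antisense_bias = 0.5,
                       n_gaps = 20,
                       gap_type_mix = c(fragment = 0.6, clone = 0.2,
                                        contig = 0.2),
                       gap_length_range = c(200, 5000),
                       unsized_gap_prob = 0.1, flank_repeat_prob = 0.3,
                       repeat_density = 30, putein_error_rate = 0.15) {
  stopifnot(n_chromosomes >= 1,
            length(chromosome_lengths) == n_chromosomes,
            all(chromosome_lengths > 0), n_ervs >= 0, n_genes >= 0,
            n_gaps >= 0, antisense_bias >= 0, antisense_bias <= 1,
            substitution_rate > 0, ltr_length >= 1, erv_spacing >= 0,
            diff(erv_length_range) >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
}

#' Mutate an ancestral LTR into a diverged 5'/3' pair
#'
#' The number of differing sites is drawn as `Binomial(L, 2 * rate *
#' age)` — each lineage accumulates substitutions at `rate * age`, and
#' sites are mutated at most once (no homoplasy), so realized pairwise
#' divergence is unbiased for twice the per-lineage expectation, matching
#' the linear molecular clock used for dating.  Each differing site is
#' assigned to one lineage at random and substituted with a different
#' base.
#'
#' @param ancestral ancestral LTR sequence (character).
#' @param age integration age in mya.
#' @param rate per-lineage substitution rate (fraction/site/mya).
#' @return list with `seq5`, `seq3`, `n_diff` (planted differing sites).
#' @export
mutate_ltr_pair <- function(ancestral, age, rate = 0.002) {
  chars <- strsplit(ancestral, "")[[1]]
  L <- length(chars)
  k <- stats::rbinom(1, L, min(1, 2 * rate * age))
  s5 <- s3 <- chars
  if (k > 0) {
    sites <- sample.int(L, k)
    to5 <- stats::runif(k) < 0.5
    if (any(to5)) s5[sites[to5]] <- mutate_base(s5[sites[to5]])
    if (any(!to5)) s3[sites[!to5]] <- mutate_base(s3[sites[!to5]])
  }
  list(seq5 = paste(s5, collapse = ""), seq3 = paste(s3, collapse = ""),
       n_diff = k)
}

random_aa <- function(n, n_x = 0) {
  aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  if (n_x > 0) aa[sample.int(n, min(n, n_x))] <- "X"
  paste(aa, collapse = "")
}

place_nonoverlapping <- function(n, len_fun, genome, occupied = NULL,
                                 pad = 0, max_tries = 200) {
  # occupied: data.frame chrom/start/end to avoid
  p_chrom <- character(0); p_start <- p_end <- numeric(0)
  if (!is.null(occupied) && nrow(occupied)) {
    p_chrom <- occupied$chrom; p_start <- occupied$start; p_end <- occupied$end
  }
  o_chrom <- character(n); o_start <- o_end <- numeric(n)
  weights <- as.numeric(genome) / sum(as.numeric(genome))
  chrom_names <- names(genome)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chrom_names, 1, prob = weights)
      len <- len_fun()
      if (len >= genome[[chrom]]) next
      start <- floor(stats::runif(1, 0, genome[[chrom]] - len))
      end <- start + len
      clash <- p_chrom == chrom & p_start < end + pad & p_end > start - pad
      if (!any(clash)) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible placement: requested features exceed genome space")
    p_chrom <- c(p_chrom, chrom); p_start <- c(p_start, start)
    p_end <- c(p_end, end)
    o_chrom[i] <- chrom; o_start[i] <- start; o_end[i] <- end
  }
  data.frame(chrom = o_chrom, start = o_start, end = o_end,
             stringsAsFactors = FALSE)
}

TRNA_LABELS <- c("Pro", "Lys", "Gly", "Leu", "Arg")

#' Simulate a full set of pipeline inputs with known ground truth
#'
#' Generates, in one deterministic pass: a genome index; a proviral chain
#' table with puteins, genus labels, PBS labels and LTR spans; the LTR
#' sequences (named `<id>_5ltr` / `<id>_3ltr`); a transcript table with
#' overlapping alternative transcripts; a background repeat track; an AGP
#' tiling with planted gaps; and a `truth` list recording every planted
#' value (true ages and divergences, gene orientations relative to their
#' ERV, gap candidacy).
#'
#' @param config a [sim_config].
#' @return list of class `sim_genome` with elements `genome`, `chains`
#'   (a [chain_table]), `ltr_seqs` (named character), `transcripts`,
#'   `repeats`, `agp`, and `truth` (list of data.frames `ervs`, `genes`,
#'   `gaps`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- genome_index(stats::setNames(config$chromosome_lengths,
                                         paste0("chr", seq_len(config$n_chromosomes))))
  ## --- ERVs with LTR pairs -------------------------------------------------
  spans <- place_nonoverlapping(config$n_ervs, function()
    floor(stats::runif(1, config$erv_length_range[1], config$erv_length_range[2] + 1)),
    genome, pad = config$erv_spacing)
  n <- config$n_ervs
  ltr_seqs <- character(0)
  ages <- divs <- numeric(n)
  chains <- NULL
  puteins <- NULL
  if (n > 0) {
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ages <- sample(config$target_ages, n, replace = TRUE)
    Lltr <- config$ltr_length
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      pair <- mutate_ltr_pair(random_dna(Lltr), ages[i], config$substitution_rate)
      divs[i] <- pair$n_diff / Lltr
      seqs[[i]] <- stats::setNames(c(pair$seq5, pair$seq3),
                                   paste0(i, c("_5ltr", "_3ltr")))
    }
    ltr_seqs <- unlist(seqs)
    chains <- data.frame(
      id = seq_len(n), chrom = spans$chrom, start = spans$start,
      end = spans$end, strand = strand,
      score = round(stats::runif(n, 310, 2000), 1),
      genus = sample(GENUS_LEVELS, n, replace = TRUE,
                     prob = c(0.7, 0.1, 0.05, 0.05, 0.1)),
      pbs = ifelse(stats::runif(n) < 0.6,
                   sample(TRNA_LABELS, n, replace = TRUE), NA_character_),
      ltr5_start = spans$start, ltr5_end = spans$start + Lltr,
      ltr3_start = spans$end - Lltr, ltr3_end = spans$end,
      stringsAsFactors = FALSE)
    present <- which(matrix(stats::runif(4L * n) < 0.7, n, 4L),
                     arr.ind = TRUE)
    present <- present[order(present[, 1], present[, 2]), , drop = FALSE]
    n_put <- nrow(present)
    puteins <- if (n_put) {
      err <- stats::runif(n_put) < config$putein_error_rate
      n_x <- ifelse(err, 5L + stats::rpois(n_put, 2), stats::rpois(n_put, 1))
      data.frame(chain_id = present[, 1], gene = PUTEIN_GENES[present[, 2]],
                 seq = vapply(n_x, function(k) random_aa(80, k), ""),
                 stringsAsFactors = FALSE)
    } else NULL
  }
  tab <- chain_table(if (is.null(chains)) empty_chain_df() else chains,
                     puteins, genome_id = "synthetic")
  ## --- genes around ERVs ---------------------------------------------------
  transcripts <- data.frame(gene_id = character(), transcript_id = character(),
                            chrom = character(), start = numeric(),
                            end = numeric(), strand = character(),
                            stringsAsFactors = FALSE)
  gene_truth <- NULL
  if (config$n_genes > 0 && n > 0) {
    ng <- config$n_genes
    ei <- sample.int(n, ng, replace = TRUE)
    anti <- stats::runif(ng) < config$antisense_bias
    erv_strand <- chains$strand[ei]
    strand_g <- ifelse(anti, ifelse(erv_strand == "+", "-", "+"), erv_strand)
    glen <- floor(stats::runif(ng, config$gene_length_range[1],
                               config$gene_length_range[2] + 1))
    offset <- floor(stats::runif(ng, -config$gene_offset_max,
                                 config$gene_offset_max))
    gstart <- ifelse(offset >= 0, chains$end[ei] + offset,
                     chains$start[ei] + offset - glen)
    gstart <- pmax(0, pmin(gstart, as.numeric(genome[chains$chrom[ei]]) - glen))
    gid <- sprintf("gene%03d", seq_len(ng))
    t_end <- gstart + glen
    primary <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".1"),
                          chrom = chains$chrom[ei], start = gstart,
                          end = t_end, strand = strand_g,
                          stringsAsFactors = FALSE)
    k <- sample(seq(config$transcripts_per_gene_range[1],
                    config$transcripts_per_gene_range[2]),
                ng, replace = TRUE)
    alt_of <- rep(seq_len(ng), pmax(0L, k - 1L))
    alts <- NULL
    if (length(alt_of)) {
      s <- floor(stats::runif(length(alt_of), gstart[alt_of],
                              t_end[alt_of] - 100))
      e <- floor(stats::runif(length(alt_of), s + 100, t_end[alt_of] + 1))
      alt_no <- stats::ave(alt_of, alt_of, FUN = seq_along) + 1L
      alts <- data.frame(gene_id = gid[alt_of],
                         transcript_id = paste0(gid[alt_of], ".", alt_no),
                         chrom = chains$chrom[ei][alt_of], start = s, end = e,
                         strand = strand_g[alt_of], stringsAsFactors = FALSE)
    }
    transcripts <- rbind(primary, alts)
    transcripts <- transcripts[order(match(transcripts$gene_id, gid),
                                     transcripts$transcript_id), ]
    rownames(transcripts) <- NULL
    gene_truth <- data.frame(gene_id = gid, erv_id = chains$id[ei],
                             antisense = anti, stringsAsFactors = FALSE)
  }
  ## --- assembly gaps -------------------------------------------------------
  gap_spans <- place_nonoverlapping(config$n_gaps, function()
    floor(stats::runif(1, config$gap_length_range[1],
                       config$gap_length_range[2] + 1)),
    genome, occupied = spans)
  gaps <- NULL; planted_flanks <- NULL
  if (config$n_gaps > 0) {
    types <- sample(names(config$gap_type_mix), config$n_gaps, replace = TRUE,
                    prob = config$gap_type_mix)
    sized <- stats::runif(config$n_gaps) >= config$unsized_gap_prob
    flanked <- stats::runif(config$n_gaps) < config$flank_repeat_prob
    gaps <- data.frame(chrom = gap_spans$chrom, start = gap_spans$start,
                       end = gap_spans$end, gap_type = types, sized = sized,
                       stringsAsFactors = FALSE)
    fl <- list()
    for (i in which(flanked)) {
      left <- stats::runif(1) < 0.5
      rlen <- 150
      rstart <- if (left) max(0, gaps$start[i] - 10 - rlen) else gaps$end[i] + 10
      fl[[length(fl) + 1L]] <- data.frame(
        chrom = gaps$chrom[i], start = rstart, end = rstart + rlen,
        class = sample(EXCLUDED_FLANK_CLASSES, 1), strand = "+",
        stringsAsFactors = FALSE)
    }
    planted_flanks <- if (length(fl)) do.call(rbind, fl) else NULL
  }
  ## --- background repeats (kept away from gap flanks) ----------------------
  reps <- list()
  for (chrom in names(genome)) {
    n_rep <- stats::rpois(1, config$repeat_density * genome[[chrom]] / 1e6)
    if (!n_rep) next
    rlen <- floor(stats::runif(n_rep, 100, 500))
    rstart <- floor(stats::runif(n_rep, 0, genome[[chrom]] - rlen))
    keep <- rep(TRUE, n_rep)
    if (!is.null(gaps)) {
      sub <- gaps[gaps$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(sub)))
        keep <- keep & !(rstart + rlen > sub$start[j] - 120 &
                           rstart < sub$end[j] + 120)
    }
    if (!any(keep)) next
    reps[[length(reps) + 1L]] <- data.frame(
      chrom = chrom, start = rstart[keep], end = (rstart + rlen)[keep],
      class = sample(REPEAT_CLASSES, sum(keep), replace = TRUE,
                     prob = c(0.4, 0.3, 0.15, 0.1, 0.05)),
      strand = sample(c("+", "-"), sum(keep), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, c(reps, list(planted_flanks)))
  if (is.null(repeats))
    repeats <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), class = character(),
                          strand = character(), stringsAsFactors = FALSE)
  repeats$name <- repeats$class
  repeats <- repeats[order(repeats$chrom, repeats$start),
                     c("chrom", "start", "end", "class", "name", "strand")]
  rownames(repeats) <- NULL
  ## --- AGP tiling and gap truth --------------------------------------------
  agp <- build_agp(genome, gaps)
  gap_truth <- NULL
  if (!is.null(gaps)) {
    planted <- logical(nrow(gaps))
    if (!is.null(planted_flanks)) {
      for (i in seq_len(nrow(gaps))) {
        pf <- planted_flanks
        planted[i] <- any(pf$chrom == gaps$chrom[i] &
                            ((pf$end > gaps$start[i] - 50 &
                                pf$start < gaps$start[i]) |
                               (pf$end > gaps$end[i] &
                                  pf$start < gaps$end[i] + 50)))
      }
    }
    gap_truth <- data.frame(
      chrom = gaps$chrom, start = gaps$start, end = gaps$end,
      gap_type = gaps$gap_type, sized = gaps$sized,
      candidate = !(gaps$gap_type %in% c("clone", "contig")) &
        (!gaps$sized | (gaps$end - gaps$start) >= 1000) & !planted,
      stringsAsFactors = FALSE)
  }
  truth <- list(
    ervs = if (n > 0) data.frame(id = seq_len(n), chrom = spans$chrom,
                                 start = spans$start, end = spans$end,
                                 age = ages, divergence = divs,
                                 stringsAsFactors = FALSE)
           else data.frame(id = integer(), age = numeric(),
                           divergence = numeric()),
    genes = if (!is.null(gene_truth)) gene_truth else
      data.frame(gene_id = character(), erv_id = integer(),
                 antisense = logical()),
    gaps = gap_truth)
  structure(list(genome = genome, chains = tab, ltr_seqs = ltr_seqs,
                 transcripts = transcripts, repeats = repeats, agp = agp,
                 truth = truth, config = config),
            class = "sim_genome")
}

build_agp <- function(genome, gaps) {
  rows <- list()
  for (chrom in names(genome)) {
    sub <- if (is.null(gaps)) NULL else {
      s <- gaps[gaps$chrom == chrom, , drop = FALSE]
      s[order(s$start), , drop = FALSE]
    }
    pos <- 0; part <- 1L; ctg <- 1L
    emit_component <- function(from, to) {
      if (to <= from) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = from, end = to, part_number = part,
        component_type = "W", is_gap = FALSE, gap_type = NA_character_,
        gap_length = NA_real_, sized = NA,
        component_id = sprintf("%s_ctg%03d", chrom, ctg), orientation = "+",
        stringsAsFactors = FALSE)
      part <<- part + 1L; ctg <<- ctg + 1L
    }
    if (!is.null(sub)) for (i in seq_len(nrow(sub))) {
      emit_component(pos, sub$start[i])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = sub$start[i], end = sub$end[i],
        part_number = part, component_type = if (sub$sized[i]) "N" else "U",
        is_gap = TRUE, gap_type = sub$gap_type[i],
        gap_length = if (sub$sized[i]) sub$end[i] - sub$start[i] else 100,
        sized = sub$sized[i], component_id = NA_character_,
        orientation = NA_character_, stringsAsFactors = FALSE)
      part <- part + 1L
      pos <- sub$end[i]
    }
    emit_component(pos, genome[[chrom]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$genome), "chromosome(s),",
      n_chains(x$chains), "ERV(s),",
      length(unique(x$transcripts$gene_id)), "gene(s),",
      sum(x$agp$is_gap), "gap(s)\n")
  invisible(x)
}

#' Write every simulated input (plus ground-truth sidecars) to a directory
#'
#' Files: `chains.tsv` (chain-table dialect), `ltrs.fasta`, `genes.gff3`,
#' `repeats.bed`, `assembly.agp`, and `truth_ervs.tsv`,
#' `truth_genes.tsv`, `truth_gaps.tsv`, `genome.tsv`.
#'
#' @param sim a `sim_genome` from [simulate_genome].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_chain_table(sim$chains, fp("chains.tsv"))
  writeLines(as.character(rbind(paste0(">", names(sim$ltr_seqs)),
                                unname(sim$ltr_seqs))), fp("ltrs.fasta"))
  write_gff_genes(sim$transcripts, fp("genes.gff3"))
  write_repeat_track(sim$repeats, fp("repeats.bed"))
  write_agp(sim$agp, fp("assembly.agp"))
  wt <- function(df, f) utils::write.table(df, fp(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(data.frame(chrom = names(sim$genome), length = as.numeric(sim$genome)),
     "genome.tsv")
  wt(sim$truth$ervs, "truth_ervs.tsv")
  wt(sim$truth$genes, "truth_genes.tsv")
  if (!is.null(sim$truth$gaps)) wt(sim$truth$gaps, "truth_gaps.tsv")
  invisible(dir)
}

#' Simulate one locus cluster of overlapping chains
#'
#' Builds a cluster of mutually overlapping chains designed to be decided
#' at a chosen stage of the one-chain-per-locus cascade, with the winner
#' recorded, or a fully random cluster (winner not designated) for use
#' against an external brute-force oracle.
#'
#' @param n_chains cluster size (>= 1; stage-designed clusters use >= 2).
#' @param stage `"putein_diversity"` (stage 1 decides),
#'   `"putein_total"` (stages tie through 1, stage 2 decides),
#'   `"score"` (tie through 2, stage 3 decides), or `"random"`.
#' @param chrom,at chromosome name and anchor coordinate.
#' @param id_start first chain id.
#' @return list with `table` (a [chain_table]) and `winner_id`
#'   (`NA` for `stage = "random"`).
#' @export
simulate_locus_cluster <- function(n_chains = 3,
                                   stage = c("putein_diversity",
                                             "putein_total", "score",
                                             "random"),
                                   chrom = "chr1", at = 10000,
                                   id_start = 1L) {
  stage <- match.arg(stage)
  stopifnot(n_chains >= 1)
  ids <- seq.int(id_start, length.out = n_chains)
  starts <- at + (seq_len(n_chains) - 1) * 500
  ends <- starts + 6000                     # pairwise overlapping spans
  chains <- data.frame(id = ids, chrom = chrom, start = starts, end = ends,
                       strand = sample(c("+", "-"), n_chains, replace = TRUE),
                       score = round(stats::runif(n_chains, 310, 1500), 1),
                       genus = "gamma", stringsAsFactors = FALSE)
  pl <- list()
  add_puteins <- function(id, genes) {
    for (g in genes)
      pl[[length(pl) + 1L]] <<- data.frame(chain_id = id, gene = g,
                                           seq = random_aa(40),
                                           stringsAsFactors = FALSE)
  }
  winner <- NA_integer_
  if (n_chains == 1) {
    add_puteins(ids[1], sample(PUTEIN_GENES, 2))
    winner <- ids[1]
  } else if (stage == "putein_diversity") {
    # winner has strictly more distinct genes than any other chain
    add_puteins(ids[1], c("gag", "pol", "env"))
    for (i in seq_len(n_chains)[-1])
      add_puteins(ids[i], rep(sample(PUTEIN_GENES, 1), 3))
    winner <- ids[1]
  } else if (stage == "putein_total") {
    # all chains tie on distinct genes (2), winner has more total puteins
    add_puteins(ids[1], c("gag", "pol", "pol", "pol"))
    for (i in seq_len(n_chains)[-1]) add_puteins(ids[i], c("gag", "pol"))
    winner <- ids[1]
  } else if (stage == "score") {
    for (i in seq_len(n_chains)) add_puteins(ids[i], c("gag", "pol"))
    chains$score <- round(seq(400, 400 + 50 * (n_chains - 1),
                              length.out = n_chains), 1)
    winner <- ids[which.max(chains$score)]
  } else {
    for (i in seq_len(n_chains)) {
      k <- sample.int(4, 1)
      add_puteins(ids[i], sample(PUTEIN_GENES, k, replace = TRUE))
    }
  }
  list(table = chain_table(chains, do.call(rbind, pl),
                           genome_id = "synthetic-cluster"),
       winner_id = winner)
}
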