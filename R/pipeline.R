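## End-to-end orchestration.
##
## Runs the full comparative analysis on a synthetic allotetraploid:
## simulation (genomes, scaffolds, anchors, reads, spiked features),
## synteny placement, pseudo-chromosome construction and A/B partitioning,
## Ks estimation and clock dating (within-genome and vs outgroup), k-mer
## genome-size estimation, SSR/marker analyses and the epitope scan.
## Every stage writes plain-text outputs into the run directory; the final
## report is assembled from those files only, so a re-run with the same
## configuration is byte-identical and a stage whose outputs already exist
## is not recomputed (delete its files to regenerate it and its
## dependents).

# extract CDS of the given gene ids from sequences, using truth coordinates
.gene_seqs <- function(seqs, truth, gene_ids) {
  gc <- truth$gene_coordinates
  gc <- gc[gc$seq_id %in% names(seqs) & gc$gene_id %in% gene_ids, ,
           drop = FALSE]
  gc <- gc[!duplicated(gc$gene_id), , drop = FALSE]
  out <- substring(unlist(seqs[gc$seq_id]), gc$start + 1L, gc$end)
  stats::setNames(out, gc$gene_id)
}

# spike SSR arrays into intergenic scaffold positions, keeping truth
# coordinates consistent; positions are rejection-sampled until the SSR is
# recovered at its exact position (repeat-free flanks)
.spike_scaffold_ssrs <- function(scaffolds, truth, n_spikes) {
  motifs <- list(c("AG", 8L), c("AC", 9L), c("AAG", 7L), c("AT", 6L),
                 c("AGC", 5L), c("AAAT", 5L), c("AGGC", 5L),
                 c("AACTG", 5L), c("ACGTAC", 5L), c("A", 12L))
  targets <- names(sort(nchar(scaffolds), decreasing = TRUE))
  gc <- truth$gene_coordinates
  done <- 0L
  ti <- 0L
  while (done < n_spikes && ti < 10L * n_spikes) {
    ti <- ti + 1L
    scf <- targets[(ti - 1L) %% length(targets) + 1L]
    len <- nchar(scaffolds[[scf]])
    genes <- gc[gc$seq_id == scf, , drop = FALSE]
    spikes_here <- truth$spiked_ssrs[truth$spiked_ssrs$seq_id == scf, ,
                                     drop = FALSE]
    mot <- motifs[[done %% length(motifs) + 1L]]
    payload <- strrep(mot[[1L]], as.integer(mot[[2L]]))
    ok_pos <- NA_integer_
    for (try in seq_len(20L)) {
      pos <- sample.int(max(1L, len - 1L), 1L)
      in_gene <- nrow(genes) && any(genes$start - 20L < pos &
                                    pos < genes$end + 20L)
      near_spike <- nrow(spikes_here) &&
        any(abs(spikes_here$position - pos) < 150L + nchar(payload))
      if (in_gene || near_spike) next
      cand <- spike_feature(scaffolds[[scf]], pos, payload)
      lo <- max(1L, pos - 40L); hi <- min(nchar(cand), pos + nchar(payload) + 40L)
      found <- find_ssrs(stats::setNames(substr(cand, lo, hi), "w"))
      hit <- found[found$kind == "simple" &
                   found$start == pos - (lo - 1L) &
                   found$motif == mot[[1L]] &
                   found$repeat_count == as.integer(mot[[2L]]), , drop = FALSE]
      if (nrow(hit) == 1L && nrow(found) == 1L) { ok_pos <- pos; break }
    }
    if (is.na(ok_pos)) next
    scaffolds[[scf]] <- spike_feature(scaffolds[[scf]], ok_pos, payload)
    plen <- nchar(payload)
    shift <- gc$seq_id == scf & gc$start >= ok_pos
    gc$start[shift] <- gc$start[shift] + plen
    gc$end[shift] <- gc$end[shift] + plen
    if (nrow(truth$spiked_ssrs)) {
      sh <- truth$spiked_ssrs$seq_id == scf &
        truth$spiked_ssrs$position >= ok_pos
      truth$spiked_ssrs$position[sh] <- truth$spiked_ssrs$position[sh] + plen
    }
    truth <- truth_add_ssr(truth, scf, ok_pos, mot[[1L]],
                           as.integer(mot[[2L]]))
    done <- done + 1L
  }
  truth$gene_coordinates <- gc
  if (done < n_spikes)
    warning("spiked only ", done, " of ", n_spikes, " requested SSRs")
  list(scaffolds = scaffolds, truth = truth)
}

.stage_done <- function(out_dir, files) {
  all(file.exists(file.path(out_dir, files)))
}

#' Run the full analysis pipeline on a synthetic allotetraploid
#'
#' Stages run in dependency order (simulate, then synteny, scaffolding and
#' molclock; kmerstats, markers and peptides are independent of the
#' synteny branch).  All outputs are plain text under `out_dir`; stages
#' whose outputs are already present are skipped unless `force = TRUE`.
#'
#' @param config a [simulation_config()]; its seed drives every stage.
#' @param out_dir run directory (created).
#' @param force recompute stages whose outputs already exist.
#' @param min_genes minimum syntenic genes per placed scaffold.
#' @param partition_threshold overlap threshold of the A/B rule.
#' @param gap_length N gap between pseudo-chromosome members.
#' @param kmer_k k-mer length for the genome-size estimate.
#' @param n_ssr_spikes SSR arrays spiked into scaffolds.
#' @param n_epitope_spikes epitopes spiked into the derived proteome
#'   (default 0: the expected epitope result is absence).
#' @param epitope_file optional epitope list; defaults to the synthetic
#'   demo set shipped in `extdata/epitopes_synthetic.txt`.
#' @return an `analysis_report` list (also written as `report.json` and
#'   `report.txt`), with a `stage_status` data.frame attached.
#' @export
run_all <- function(config = simulation_config(), out_dir,
                    force = FALSE, min_genes = 3L,
                    partition_threshold = 0.75, gap_length = 100L,
                    kmer_k = 21L, n_ssr_spikes = 10L,
                    n_epitope_spikes = 0L, epitope_file = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  note <- function(stage, state) {
    status[[length(status) + 1L]] <<- data.frame(stage = stage,
                                                 status = state)
  }

  ## -- stage: simulate ---------------------------------------------------
  sim_files <- c("genome_a.fasta", "genome_b.fasta", "outgroup.fasta",
                 "scaffolds.fasta", "anchors.tsv", "reads.fasta",
                 "truth/homeolog_pairs.tsv")
  if (force || !.stage_done(out_dir, sim_files)) {
    sim <- simulate_allotetraploid(config)
    frag <- with_seed(config$seed + 1L,
      fragment_genome(c(sim$genome_a, sim$genome_b),
                      config$scaffold_mean_length_bp, sim$truth))
    scaffolds <- frag$scaffolds
    truth <- frag$truth
    if (n_ssr_spikes > 0L) {
      sp <- with_seed(config$seed + 2L,
        .spike_scaffold_ssrs(scaffolds, truth, n_ssr_spikes))
      scaffolds <- sp$scaffolds
      truth <- sp$truth
    }
    anchors <- make_anchor_table(truth, config$anchor_dropout,
                                 seed = config$seed + 3L)
    reads <- simulate_reads(c(sim$genome_a, sim$genome_b),
                            config$read_depth, config$read_length_bp,
                            seed = config$seed + 4L)
    write_fasta(sim$genome_a, file.path(out_dir, "genome_a.fasta"))
    write_fasta(sim$genome_b, file.path(out_dir, "genome_b.fasta"))
    write_fasta(sim$outgroup, file.path(out_dir, "outgroup.fasta"))
    write_fasta(scaffolds, file.path(out_dir, "scaffolds.fasta"))
    write_anchor_table(anchors, file.path(out_dir, "anchors.tsv"))
    write_fasta(reads, file.path(out_dir, "reads.fasta"))
    write_truth_table(truth, file.path(out_dir, "truth"))
    note("simulate", "run")
  } else note("simulate", "cached")
  genome_a <- read_fasta(file.path(out_dir, "genome_a.fasta"))
  genome_b <- read_fasta(file.path(out_dir, "genome_b.fasta"))
  outgroup <- read_fasta(file.path(out_dir, "outgroup.fasta"))
  scaffolds <- read_fasta(file.path(out_dir, "scaffolds.fasta"))
  truth <- read_truth_table(file.path(out_dir, "truth"))

  ## -- stage: synteny ----------------------------------------------------
  if (force || !.stage_done(out_dir, "placements.tsv")) {
    anchors <- read_anchor_table(file.path(out_dir, "anchors.tsv"))
    placements <- place_scaffolds(anchors, min_genes = min_genes,
                                  scaffold_lengths = nchar(scaffolds))
    write_tsv(placements, file.path(out_dir, "placements.tsv"))
    note("synteny", "run")
  } else note("synteny", "cached")
  placements <- read_tsv(file.path(out_dir, "placements.tsv"))

  ## -- stage: scaffolding ------------------------------------------------
  scf_files <- c("partition.tsv", "pseudo.fasta", "pseudo.agp",
                 "pseudo_layout.tsv")
  if (force || !.stage_done(out_dir, scf_files)) {
    parts <- list(); seqs <- character(0); agps <- list(); layouts <- list()
    for (chrom in sort(unique(placements$ref_chrom))) {
      pc <- placements[placements$ref_chrom == chrom, , drop = FALSE]
      pc <- order_scaffolds(pc)
      lab <- greedy_partition(pc, threshold = partition_threshold)
      lab$ref_chrom <- chrom
      parts[[chrom]] <- lab
      pname <- sub("^ref_chr", "pseudo", chrom)
      pseudo <- build_pseudochromosome(pc, scaffolds,
                                       gap_length = gap_length,
                                       name = pname)
      seqs[[pname]] <- pseudo$sequence
      agps[[pname]] <- pseudo$agp
      lay <- pseudo$layout
      lay$object <- pname
      layouts[[pname]] <- lay
      for (side in c("A", "B")) {
        mem <- pc[pc$scaffold_id %in% lab$scaffold_id[lab$label == side], ,
                  drop = FALSE]
        if (!nrow(mem)) next
        sp <- build_pseudochromosome(mem, scaffolds,
                                     gap_length = gap_length,
                                     name = paste0(pname, "_", side))
        seqs[[sp$name]] <- sp$sequence
        agps[[sp$name]] <- sp$agp
      }
    }
    write_tsv(do.call(rbind, unname(parts)), file.path(out_dir, "partition.tsv"))
    write_fasta(seqs, file.path(out_dir, "pseudo.fasta"))
    write_agp(do.call(rbind, unname(agps)), file.path(out_dir, "pseudo.agp"))
    write_tsv(do.call(rbind, unname(layouts)),
              file.path(out_dir, "pseudo_layout.tsv"))
    note("scaffolding", "run")
  } else note("scaffolding", "cached")
  partition <- read_tsv(file.path(out_dir, "partition.tsv"))
  layout <- read_tsv(file.path(out_dir, "pseudo_layout.tsv"))

  ## -- stage: molclock ---------------------------------------------------
  if (force || !.stage_done(out_dir, c("ks_within.tsv", "ks_outgroup.tsv"))) {
    hp <- truth$homeolog_pairs
    cds_a <- .gene_seqs(genome_a, truth, hp$gene_a)
    cds_b <- .gene_seqs(genome_b, truth, hp$gene_b)
    ks_within <- ng86_pairs(cds_a[hp$gene_a], cds_b[hp$gene_b],
                            pair_ids = paste(hp$gene_a, hp$gene_b))
    write_tsv(ks_within, file.path(out_dir, "ks_within.tsv"))
    ref_ids <- sub("^gA_", "gR_", hp$gene_a)
    cds_r <- .gene_seqs(outgroup, truth, ref_ids)
    ks_out <- ng86_pairs(cds_a[hp$gene_a], cds_r[ref_ids],
                         pair_ids = paste(hp$gene_a, ref_ids))
    write_tsv(ks_out, file.path(out_dir, "ks_outgroup.tsv"))
    note("molclock", "run")
  } else note("molclock", "cached")
  ks_within <- read_tsv(file.path(out_dir, "ks_within.tsv"))
  ks_out <- read_tsv(file.path(out_dir, "ks_outgroup.tsv"))

  ## -- stage: kmerstats --------------------------------------------------
  if (force || !.stage_done(out_dir, "genomesize.tsv")) {
    reads <- read_fasta(file.path(out_dir, "reads.fasta"))
    gs <- genome_size_from_reads(reads, k = kmer_k)
    write_tsv(gs$histogram$histogram, file.path(out_dir, "kmer_hist.tsv"))
    write_tsv(data.frame(k = kmer_k, M = gs$M, N = gs$N, G = gs$G,
                         total_bases = gs$histogram$total_bases,
                         read_length = gs$histogram$read_length),
              file.path(out_dir, "genomesize.tsv"))
    note("kmerstats", "run")
  } else note("kmerstats", "cached")
  gs <- read_tsv(file.path(out_dir, "genomesize.tsv"))

  ## -- stage: markers ----------------------------------------------------
  mk_files <- c("ssr.tsv", "ssr.bed", "map_assignments.tsv",
                "cm_per_mbp.tsv")
  if (force || !.stage_done(out_dir, mk_files)) {
    ssrs <- find_ssrs(scaffolds)
    write_tsv(ssrs, file.path(out_dir, "ssr.tsv"))
    write_ssr_bed(ssrs, file.path(out_dir, "ssr.bed"))
    # synthetic genetic map: every 5th reference gene is a marker; map
    # distances grow 1.5 cM per gene index along each linkage group
    gc <- truth$gene_coordinates
    refs <- gc[grepl("^gR_", gc$gene_id), , drop = FALSE]
    refs$idx <- as.integer(sub("^.*_g", "", refs$gene_id))
    refs <- refs[refs$idx %% 5L == 0L, , drop = FALSE]
    map <- data.frame(marker_id = sub("^gR_", "m_", refs$gene_id),
                      linkage_group = sub("^ref_chr", "LG", refs$seq_id),
                      position = refs$idx * 1.5)
    write.csv(map[, c("marker_id", "linkage_group", "position")],
              file.path(out_dir, "genetic_map.csv"), row.names = FALSE,
              quote = FALSE)
    # physical marker positions: the A-subgenome gene copy lifted onto its
    # combined pseudo-chromosome
    a_ids <- sub("^m_", "gA_", map$marker_id)
    scf_rows <- gc[gc$gene_id %in% a_ids &
                   gc$seq_id %in% names(truth$scaffold_to_subgenome), ,
                   drop = FALSE]
    lay_by_obj <- split(layout, layout$object)
    mrows <- list()
    for (i in seq_len(nrow(scf_rows))) {
      scf <- scf_rows$seq_id[i]
      obj <- layout$object[match(scf, layout$scaffold_id)]
      if (is.na(obj) || grepl("_[AB]$", obj)) next
      bp <- lift_to_pseudo(lay_by_obj[[obj]], scf, scf_rows$start[i])
      mrows[[length(mrows) + 1L]] <- data.frame(
        marker_id = sub("^gA_", "m_", scf_rows$gene_id[i]),
        pseudo_chromosome = obj, bp = bp)
    }
    mloc <- if (length(mrows)) do.call(rbind, mrows) else
      data.frame(marker_id = character(0), pseudo_chromosome = character(0),
                 bp = numeric(0))
    write_tsv(mloc, file.path(out_dir, "marker_placements.tsv"))
    assign <- assign_linkage_groups(mloc, map)
    write_tsv(assign, file.path(out_dir, "map_assignments.tsv"))
    mm <- merge(merge(mloc, map, by = "marker_id"), assign["linkage_group"],
                by = "linkage_group")
    names(mm)[names(mm) == "position"] <- "cm"
    ratios <- cm_per_mbp(mm)
    write_tsv(ratios, file.path(out_dir, "cm_per_mbp.tsv"))
    note("markers", "run")
  } else note("markers", "cached")
  ssrs <- read_tsv(file.path(out_dir, "ssr.tsv"))
  assign <- read_tsv(file.path(out_dir, "map_assignments.tsv"))
  ratios <- read_tsv(file.path(out_dir, "cm_per_mbp.tsv"))

  ## -- stage: peptides ---------------------------------------------------
  if (force || !.stage_done(out_dir, c("epitope_matches.tsv",
                                       "epitope_summary.tsv"))) {
    cds_a <- .gene_seqs(genome_a, truth, truth$homeolog_pairs$gene_a)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds_a), no.init.codon = TRUE))
    prot <- gsub("*", "", prot, fixed = TRUE)
    names(prot) <- sub("^gA_", "p_", names(cds_a))
    if (is.null(epitope_file))
      epitope_file <- system.file("extdata", "epitopes_synthetic.txt",
                                  package = "tetrakit")
    epitopes <- read_epitopes(epitope_file)
    if (n_epitope_spikes > 0L) {
      sel <- with_seed(config$seed + 5L, {
        data.frame(p = sample(names(prot), n_epitope_spikes, replace = FALSE),
                   e = epitopes[(seq_len(n_epitope_spikes) - 1L) %%
                                length(epitopes) + 1L])
      })
      for (i in seq_len(nrow(sel))) {
        pos <- nchar(prot[[sel$p[i]]]) %/% 2L
        prot[[sel$p[i]]] <- spike_feature(prot[[sel$p[i]]], pos, sel$e[i])
        truth <- truth_add_epitope(truth, sel$p[i], pos, sel$e[i])
      }
      write_truth_table(truth, file.path(out_dir, "truth"))
    }
    write_fasta(prot, file.path(out_dir, "proteome.fasta"))
    matches <- scan_proteome(prot, epitopes)
    write_tsv(matches, file.path(out_dir, "epitope_matches.tsv"))
    summ <- summarize_by_species(matches,
      stats::setNames(rep("synthetic_tef", length(prot)), names(prot)))
    write_tsv(summ, file.path(out_dir, "epitope_summary.tsv"))
    note("peptides", "run")
  } else note("peptides", "cached")
  matches <- read_tsv(file.path(out_dir, "epitope_matches.tsv"))
  ep_summary <- read_tsv(file.path(out_dir, "epitope_summary.tsv"))

  ## -- report ------------------------------------------------------------
  placed_bp <- sum(nchar(scaffolds[placements$scaffold_id]))
  ab_counts <- as.data.frame(table(partition$ref_chrom, partition$label))
  names(ab_counts) <- c("ref_chrom", "label", "n")
  hp <- truth$homeolog_pairs
  idpairs <- Map(c, .gene_seqs(genome_a, truth, hp$gene_a)[hp$gene_a],
                 .gene_seqs(genome_b, truth, hp$gene_b)[hp$gene_b])
  mode_within <- ks_mode(ks_within$dS)
  mode_out <- ks_mode(ks_out$dS)
  recall <- NA_real_
  if (nrow(truth$spiked_ssrs)) {
    found <- mapply(function(sid, pos, motif, nrep) {
      any(ssrs$sequence_id == sid & ssrs$start <= pos &
            ssrs$end >= pos + nchar(motif) * nrep)
    }, truth$spiked_ssrs$seq_id, truth$spiked_ssrs$position,
       truth$spiked_ssrs$motif, truth$spiked_ssrs$repeat_count)
    recall <- mean(found)
  }
  report <- structure(list(
    placements = list(scaffolds_placed = nrow(placements),
                      bp_placed = placed_bp,
                      scaffolds_total = length(scaffolds)),
    partition = list(ab_counts = ab_counts,
                     ab_identity_pct = ab_identity(idpairs)),
    ks = list(within_mode = mode_within,
              within_date_my = date_from_ks_my(mode_within),
              outgroup_mode = mode_out,
              outgroup_date_my = date_from_ks_my(mode_out),
              n_pairs = nrow(ks_within)),
    genome_size = list(k = gs$k, M = gs$M, N = gs$N, G = gs$G,
                       true_size = sum(nchar(c(genome_a, genome_b)))),
    ssr = list(n = nrow(ssrs),
               density_bp_per_ssr = ssr_density(scaffolds, ssrs,
                                                min_motif_length = 2L),
               spiked = nrow(truth$spiked_ssrs), spike_recall = recall),
    markers = list(linkage_groups_assigned = sum(!is.na(assign$pseudo_chromosome)),
                   cm_per_mbp_range = if (nrow(ratios))
                     range(ratios$cm_per_mbp, na.rm = TRUE) else c(NA, NA)),
    epitopes = list(n_matches = nrow(matches), by_species = ep_summary)
  ), class = "analysis_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  status <- do.call(rbind, status)
  write_tsv(status, file.path(out_dir, "stage_status.tsv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  attr(report, "stage_status") <- status
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== analysis report ==\n")
  cat(sprintf("placements: %d scaffolds (%d of total), %d bp\n",
              x$placements$scaffolds_placed, x$placements$scaffolds_total,
              x$placements$bp_placed))
  cat(sprintf("A/B identity: %.2f%%\n", x$partition$ab_identity_pct))
  cat(sprintf("Ks within-genome: mode %.2f -> %d MY (n=%d pairs)\n",
              x$ks$within_mode, x$ks$within_date_my, x$ks$n_pairs))
  cat(sprintf("Ks vs outgroup:   mode %.2f -> %d MY\n",
              x$ks$outgroup_mode, x$ks$outgroup_date_my))
  cat(sprintf("genome size: M=%d N=%.2f G=%.0f bp (truth %d bp)\n",
              x$genome_size$M, x$genome_size$N, x$genome_size$G,
              x$genome_size$true_size))
  cat(sprintf("SSRs: %d found, density %.0f bp/SSR, spike recall %.2f\n",
              x$ssr$n, x$ssr$density_bp_per_ssr,
              ifelse(is.na(x$ssr$spike_recall), NA, x$ssr$spike_recall)))
  cat(sprintf("linkage groups assigned: %d; cM/Mbp range %.3f-%.3f\n",
              x$markers$linkage_groups_assigned,
              x$markers$cm_per_mbp_range[1L], x$markers$cm_per_mbp_range[2L]))
  cat(sprintf("epitope matches: %d\n", x$epitopes$n_matches))
  invisible(x)
}
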