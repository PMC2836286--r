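#' Run configuration for the full pipeline
#'
#' Bundles the inputs and the analysis thresholds. All thresholds default
#' to the conventional screening values used throughout the package: a
#' 100-aa minimum ORF, ortholog screen 60\% identity / 20\% length
#' difference / E <= 1e-20, remnant screen 30\% / 15 aa / E < 1e-3,
#' per-codon chi-square alpha 0.001, dinucleotide over/under cutoffs
#' 1.23 / 0.78, and a 10 kb GC-skew window. Unknown keys are rejected and
#' every threshold is echoed into the run manifest.
#'
#' @param panels named list of genome inputs, each a list with
#'   \code{genome} and \code{annotations} (from \code{\link{read_genbank}},
#'   \code{\link{read_fasta_genome}} or \code{\link{simulate_genome}}).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed used for every stochastic step.
#' @param reference_proteome optional named character vector of proteins
#'   used as the standardization reference; default: the first panel
#'   member's proteome.
#' @param groups optional named character vector of group labels per
#'   genome (for the dinucleotide group summary).
#' @param dnds_genomes optional character vector of exactly three genome
#'   ids for the positive-selection Venn stage; default: the first three.
#' @param synteny_pairs optional 2-column matrix/data.frame of genome-id
#'   pairs; default: consecutive panel pairs.
#' @param remnant_genomes genome ids subjected to the remnant search
#'   (default: all).
#' @param min_aa,ortholog_identity,ortholog_len_diff,ortholog_evalue
#'   thresholds; see description.
#' @param remnant_identity,remnant_aa,remnant_evalue remnant screen.
#' @param chisq_alpha,dinuc_over,dinuc_under,skew_window more thresholds.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(panels, out_dir, seed,
                       reference_proteome = NULL, groups = NULL,
                       dnds_genomes = NULL, synteny_pairs = NULL,
                       remnant_genomes = NULL,
                       min_aa = 100L,
                       ortholog_identity = 60, ortholog_len_diff = 0.20,
                       ortholog_evalue = 1e-20,
                       remnant_identity = 30, remnant_aa = 15,
                       remnant_evalue = 1e-3,
                       chisq_alpha = 0.001,
                       dinuc_over = 1.23, dinuc_under = 0.78,
                       skew_window = 10000L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, function(p) p$genome$id, "")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal newick serialization of an hclust tree
.hclust_newick <- function(hc) {
  rec <- function(i) {
    if (i < 0) return(hc$labels[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    len <- function(k) h - if (k < 0) 0 else hc$height[k]
    sprintf("(%s:%g,%s:%g)", rec(kids[1L]), len(kids[1L]),
            rec(kids[2L]), len(kids[2L]))
  }
  paste0(rec(nrow(hc$merge)), ";")
}

#' Run the full signature pipeline over a genome panel
#'
#' Executes every stage end-to-end and writes plot-ready TSV/JSON
#' artifacts: genome composition summary, per-genome replichore maps,
#' per-gene ordination coordinates with strand classes, codon-level
#' strand-asymmetry chi-square tables, dinucleotide signature profiles,
#' standardized amino-acid usage with a single-linkage dendrogram, core
#' ortholog groups, dN/dS with a positive-selection Venn partition,
#' synteny pair lines with breakpoint counts, intergenic/remnant tables,
#' and a machine-readable manifest. Stages whose preconditions are not met
#' (e.g. the Venn partition with fewer than three genomes) are skipped
#' with a notice in the manifest; any stage error aborts with a
#' stage-labelled message, retaining partial outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the in-memory results of every stage and
#'   \code{files}, the paths written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()
  notices <- character()
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  panels <- config$panels
  ids <- names(panels)
  if (length(ids) < 2L) stop("comparative stages need >= 2 genomes")

  # 1. genome composition summary
  res$composition <- stage("composition",
    composition_report(panels, out("genome_summary.tsv")))
  files <- c(files, out("genome_summary.tsv"))

  # 2. replichore maps
  res$replichore <- stage("replichore", {
    maps <- list()
    for (id in ids) {
      p <- panels[[id]]
      prof <- gc_skew_profile(p$genome, window = config$skew_window)
      ot <- predict_ori_ter(prof)
      m <- replichore_map(p$genome, p$annotations, ot$oriC, ot$ter)
      .write_tsv(m$classes, out(sprintf("replichore_%s.tsv", id)))
      maps[[id]] <- m
    }
    files <- c(files, out(sprintf("replichore_%s.tsv", ids)))
    maps
  })

  # 3. coding sets, RSCU + ordination + strand chi-square
  res$coa <- stage("codon_usage", {
    summ <- list(); coa <- list()
    for (id in ids) {
      p <- panels[[id]]
      cds <- extract_cds(p$genome, p$annotations, min_aa = config$min_aa)
      counts <- count_codons(cds)
      rs <- rscu(counts)
      ca <- correspondence_analysis(rs, k = 4L)
      tp <- gc3s_gt3s(counts)
      cls <- res$replichore[[id]]$classes
      strand_class <- cls$strand_class[match(cds$gene_id, cls$gene_id)]
      per_gene <- data.frame(gene_id = cds$gene_id,
                             ca$row_coords,
                             gc3s = tp$gc3s, gt3s = tp$gt3s,
                             strand_class = strand_class,
                             stringsAsFactors = FALSE)
      .write_tsv(per_gene, out(sprintf("coa_genes_%s.tsv", id)))
      r_gc3 <- axis_trait_correlation(ca, tp$gc3s)
      r_gt3 <- axis_trait_correlation(ca, tp$gt3s)
      lead <- counts[strand_class == "leading", , drop = FALSE]
      lagg <- counts[strand_class == "lagging", , drop = FALSE]
      chis <- strand_codon_chisq(lead, lagg, alpha = config$chisq_alpha)
      .write_tsv(chis, out(sprintf("strand_chisq_%s.tsv", id)))
      summ[[id]] <- data.frame(
        genome = id, orf_count = nrow(cds),
        axis1_inertia_pct = ca$inertia_pct[1L],
        axis2_inertia_pct = ca$inertia_pct[2L],
        r_axis1_gc3 = r_gc3[1L], r_axis1_gt3 = r_gt3[1L],
        r_axis2_gc3 = r_gc3[2L], r_axis2_gt3 = r_gt3[2L],
        sig_codons = sum(chis$significant), stringsAsFactors = FALSE)
      coa[[id]] <- list(ca = ca, per_gene = per_gene, chisq = chis,
                        counts = counts, cds = cds)
    }
    files <- c(files, out(sprintf("coa_genes_%s.tsv", ids)),
                out(sprintf("strand_chisq_%s.tsv", ids)))
    summary <- do.call(rbind, summ)
    .write_tsv(summary, out("coa_summary.tsv"))
    files <- c(files, out("coa_summary.tsv"))
    list(summary = summary, per_genome = coa)
  })

  # 4. dinucleotide signatures
  res$dinuc <- stage("genome_signature", {
    grp <- if (is.null(config$groups)) NULL else config$groups[ids]
    pt <- profile_table(panels, groups = grp, over = config$dinuc_over,
                        under = config$dinuc_under)
    .write_tsv(pt$profiles, out("dinucleotide_profiles.tsv"))
    files <- c(files, out("dinucleotide_profiles.tsv"))
    pt
  })

  # 5. amino-acid usage standardization + clustering
  res$usage <- stage("proteome_traits", {
    proteomes <- lapply(ids, function(id)
      res$coa$per_genome[[id]]$cds$protein)
    names(proteomes) <- ids
    usages <- lapply(proteomes, amino_acid_usage)
    ref <- if (is.null(config$reference_proteome)) usages[[1L]] else
      amino_acid_usage(config$reference_proteome)
    std <- lapply(usages, standardize_usage, ref_usage = ref)
    cl <- cluster_usage(std)
    mat <- data.frame(genome = rownames(cl$matrix), cl$matrix,
                      stringsAsFactors = FALSE, check.names = FALSE)
    .write_tsv(mat, out("aa_usage_standardized.tsv"))
    writeLines(.hclust_newick(cl$tree), out("aa_usage_dendrogram.nwk"))
    files <- c(files, out("aa_usage_standardized.tsv"),
                out("aa_usage_dendrogram.nwk"))
    idx <- protein_indices(stats::setNames(
      unlist(proteomes, use.names = FALSE),
      unlist(lapply(ids, function(id) res$coa$per_genome[[id]]$cds$gene_id))))
    idx$genome <- rep(ids, vapply(proteomes, length, 0L))
    means <- do.call(rbind, lapply(split(idx, idx$genome), function(d)
      data.frame(genome = d$genome[1L], n = nrow(d),
                 gravy = mean(d$gravy), aromaticity = mean(d$aromaticity),
                 pI = mean(d$pI), instability = mean(d$instability),
                 helix_pct = mean(d$helix_pct),
                 sheet_pct = mean(d$sheet_pct),
                 coil_pct = mean(d$coil_pct), stringsAsFactors = FALSE)))
    .write_tsv(means, out("protein_index_means.tsv"))
    files <- c(files, out("protein_index_means.tsv"))
    list(cluster = cl, standardized = std, index_means = means)
  })

  # 6. orthologs: hit table, screen, RBH, core cliques
  res$orthologs <- stage("orthologs", {
    proteomes <- lapply(ids, function(id) {
      cds <- res$coa$per_genome[[id]]$cds
      stats::setNames(cds$protein, cds$gene_id)
    })
    names(proteomes) <- ids
    hits <- make_hit_table(proteomes)
    gene_genome <- unlist(lapply(ids, function(id)
      stats::setNames(rep(id, length(proteomes[[id]])),
                      names(proteomes[[id]]))))
    rbh <- filter_ortholog_hits(hits, gene_genome,
                                min_identity = config$ortholog_identity,
                                max_len_diff = config$ortholog_len_diff,
                                max_evalue = config$ortholog_evalue)
    core <- build_core_set(rbh, gene_genome, ids)
    .write_tsv(core, out("core_orthologs.tsv"))
    files <- c(files, out("core_orthologs.tsv"))
    list(hits = hits, rbh = rbh, core = core, gene_genome = gene_genome)
  })

  # 7. dN/dS + positive-selection Venn (needs >= 3 genomes and core groups)
  res$selection <- stage("selection", {
    core <- res$orthologs$core
    if (length(ids) < 3L || nrow(core) == 0L) {
      notices <- c(notices,
                    "selection stage skipped: needs >= 3 genomes with core orthologs")
      NULL
    } else {
      trio <- config$dnds_genomes %||% ids[1:3]
      cds_of <- function(id) {
        cds <- res$coa$per_genome[[id]]$cds
        stats::setNames(cds$cds, cds$gene_id)
      }
      pair_tables <- list()
      for (pr in list(trio[c(1, 2)], trio[c(1, 3)], trio[c(2, 3)])) {
        ests <- lapply(seq_len(nrow(core)), function(i) {
          ca <- cds_of(pr[1L])[[core[[pr[1L]]][i]]]
          cb <- cds_of(pr[2L])[[core[[pr[2L]]][i]]]
          if (is.null(ca) || is.null(cb))
            return(data.frame(group_id = core$group_id[i], dN = NA_real_,
                              dS = NA_real_, omega = NA_real_,
                              flag = "missing", stringsAsFactors = FALSE))
          e <- dnds_modified_ng(codon_align_pair(ca, cb))
          data.frame(group_id = core$group_id[i], dN = e$dN, dS = e$dS,
                     omega = e$omega, flag = e$flag, stringsAsFactors = FALSE)
        })
        pair_tables[[paste(pr, collapse = "_")]] <- do.call(rbind, ests)
      }
      all_tab <- do.call(rbind, Map(function(nm, df) {
        df$pair <- nm; df
      }, names(pair_tables), pair_tables))
      .write_tsv(all_tab, out("dnds.tsv"))
      venn <- positive_selection_partition(pair_tables)
      jsonlite::write_json(
        list(per_pair = as.list(venn$per_pair),
             venn = as.list(venn$venn),
             computable = as.list(venn$computable)),
        out("positive_selection_venn.json"), auto_unbox = TRUE)
      files <- c(files, out("dnds.tsv"), out("positive_selection_venn.json"))
      list(pairs = pair_tables, venn = venn)
    }
  })

  # 8. synteny pair lines
  res$synteny <- stage("synteny", {
    core <- res$orthologs$core
    if (nrow(core) == 0L) {
      notices <- c(notices, "synteny stage skipped: no core orthologs")
      NULL
    } else {
      prs <- config$synteny_pairs %||%
        cbind(ids[-length(ids)], ids[-1L])
      out_list <- list()
      for (k in seq_len(nrow(prs))) {
        a <- prs[k, 1L]; b <- prs[k, 2L]
        coords <- function(id) {
          cds <- res$coa$per_genome[[id]]$cds
          cds[, c("gene_id", "start", "end", "strand")]
        }
        sc <- synteny_compare(
          data.frame(gene_a = core[[a]], gene_b = core[[b]],
                     stringsAsFactors = FALSE),
          coords(a), coords(b),
          res$replichore[[a]], res$replichore[[b]])
        f <- out(sprintf("synteny_%s_%s.tsv", a, b))
        .write_tsv(sc$pairs, f)
        files <- c(files, f)
        out_list[[paste(a, b, sep = "_")]] <- sc
      }
      out_list
    }
  })

  # 9. intergenic + remnant screen
  res$remnants <- stage("remnants", {
    rg <- config$remnant_genomes %||% ids
    summ <- list(); tabs <- list()
    for (id in rg) {
      p <- panels[[id]]
      ig <- extract_intergenic(p$genome, p$annotations)
      cds <- res$coa$per_genome[[id]]$cds
      prot <- stats::setNames(cds$protein, cds$gene_id)
      hits <- naive_translated_search(ig$segments, p$genome, prot)
      fr <- filter_remnant_hits(hits, ig$segments, p$genome,
                                min_identity = config$remnant_identity,
                                min_aa = config$remnant_aa,
                                max_evalue = config$remnant_evalue)
      comp <- res$composition[res$composition$genome == id, ]
      summ[[id]] <- data.frame(
        genome = id, n_hits = fr$summary$n_hits,
        remnant_gc_pct = fr$summary$mean_gc_pct,
        remnant_gc_sd = fr$summary$sd_gc_pct,
        intergenic_gc_pct = comp$intergenic_gc_pct,
        coding_gc_pct = comp$coding_gc_pct,
        genomic_gc_pct = comp$genomic_gc_pct, stringsAsFactors = FALSE)
      if (nrow(fr$remnants))
        tabs[[id]] <- cbind(genome = id, fr$remnants)
    }
    remnant_summary <- do.call(rbind, summ)
    .write_tsv(remnant_summary, out("remnant_summary.tsv"))
    files <- c(files, out("remnant_summary.tsv"))
    if (length(tabs)) {
      .write_tsv(do.call(rbind, tabs), out("remnant_hits.tsv"))
      files <- c(files, out("remnant_hits.tsv"))
    }
    list(summary = remnant_summary,
         hits = if (length(tabs)) do.call(rbind, tabs) else NULL)
  })

  # 10. manifest
  thresholds <- config[c("min_aa", "ortholog_identity", "ortholog_len_diff",
                         "ortholog_evalue", "remnant_identity", "remnant_aa",
                         "remnant_evalue", "chisq_alpha", "dinuc_over",
                         "dinuc_under", "skew_window")]
  manifest <- list(
    package = "ecosig",
    version = as.character(utils::packageVersion("ecosig")),
    seed = config$seed, genomes = ids, thresholds = thresholds,
    notices = notices, files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  res$files <- c(files, out("manifest.json"))
  invisible(res)
}
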