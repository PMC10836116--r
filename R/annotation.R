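#' Gene models for PAC annotation
#'
#' A light container holding one row per gene (gene_id, chrom, strand, span
#' start/end, tx_end3 = genomic coordinate of the 3' terminus of the longest
#' transcript, cds_end, and the longest-3'UTR interval utr3_start..utr3_end)
#' plus an exon table (gene_id, start, end). [simulate_genome()] output can
#' be passed directly: \code{gene_models(sim$genes, sim$exons)}.
#'
#' @param genes per-gene table (see [simulate_genome()]).
#' @param exons per-exon table.
#' @return object of class "gene_models".
#' @export
gene_models <- function(genes, exons) {
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  need <- c("gene_id", "chrom", "strand", "start", "end", "tx_end3",
            "utr3_start", "utr3_end")
  if (!all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Build gene models from a GTF/GFF file
#'
#' Uses exon features for the gene span and transcript 3' end, and CDS
#' features (when present) for the stop-codon side of the longest 3'UTR.
#' Genes without CDS annotation get an empty 3'UTR (terminal assignment
#' still applies).
#'
#' @param path GTF/GFF path.
#' @return a [gene_models()] object.
#' @export
gene_models_from_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  exdt <- data.table::data.table(
    gene_id = S4Vectors::mcols(ex)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
  genes <- exdt[, .(chrom = chrom[1], strand = strand[1],
                    start = min(start), end = max(end),
                    tx_end3 = if (strand[1] == "+") max(end) else min(start)),
                by = gene_id]
  cds <- gr[md$type == "CDS"]
  if (length(cds)) {
    cdt <- data.table::data.table(
      gene_id = S4Vectors::mcols(cds)$gene_id,
      strand = as.character(GenomicRanges::strand(cds)),
      start = GenomicRanges::start(cds), end = GenomicRanges::end(cds))
    cdt <- cdt[, .(cds_end = if (strand[1] == "+") max(end) else min(start)),
               by = gene_id]
    genes <- merge(genes, cdt, by = "gene_id", all.x = TRUE)
  } else genes[, cds_end := NA_integer_]
  genes[, utr3_start := ifelse(is.na(cds_end), NA_integer_,
                               ifelse(strand == "+", cds_end + 1L, tx_end3))]
  genes[, utr3_end := ifelse(is.na(cds_end), NA_integer_,
                             ifelse(strand == "+", tx_end3, cds_end - 1L))]
  gene_models(genes, exdt[, .(gene_id, start, end)])
}

region_levels <- c("utr3_terminal", "utr3_internal", "internal_exon",
                   "intron", "utr3_distal", "intergenic")

#' Annotate PACs with gene and region category
#'
#' Matches each PAC summit against same-strand gene models and assigns one
#' mutually exclusive region with the precedence utr3_terminal >
#' utr3_internal > internal_exon > intron > utr3_distal > intergenic:
#' within \code{terminal_tol_nt} of the longest transcript 3' end ->
#' utr3_terminal; inside the longest 3'UTR -> utr3_internal; inside an exon
#' -> internal_exon; inside the gene body otherwise -> intron; within
#' \code{distal_window_nt} downstream of the transcript end (and not inside
#' any gene) -> utr3_distal; else intergenic. When several genes qualify at
#' the same precedence the one with the nearest transcript 3' end wins.
#' Strand-mismatched overlaps are ignored (antisense calling is out of
#' scope). \code{apa_index} numbers each gene's PACs in transcript
#' orientation (5' to 3').
#'
#' @param pacs a \code{pac_set} (or its \code{info} table).
#' @param genes a [gene_models()] object.
#' @param terminal_tol_nt tolerance around the transcript 3' end (default 25,
#'   the cluster window).
#' @param distal_window_nt downstream window for distal PASs (default 5000).
#' @return data.table: pac_id, gene_id ("INTERGENIC" when unassigned),
#'   region, apa_index.
#' @export
annotate_pacs <- function(pacs, genes, terminal_tol_nt = 25L,
                          distal_window_nt = 5000L) {
  info <- if (inherits(pacs, "pac_set")) pacs$info
          else data.table::as.data.table(pacs)
  g <- genes$genes
  # candidate pac x gene pairs: summit within the gene span extended
  # downstream by the distal window, same strand
  ext_start <- ifelse(g$strand == "+", g$start,
                      pmin(g$start, g$tx_end3 - distal_window_nt))
  ext_end <- ifelse(g$strand == "+", pmax(g$end, g$tx_end3 + distal_window_nt),
                    g$end)
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(ext_start, ext_end),
                                strand = g$strand)
  pgr <- GenomicRanges::GRanges(info$chrom,
                                IRanges::IRanges(info$summit, info$summit),
                                strand = info$strand)
  hits <- GenomicRanges::findOverlaps(pgr, ggr)
  ann <- data.table::data.table(pac_id = info$pac_id,
                                gene_id = "INTERGENIC",
                                region = "intergenic")
  if (length(hits)) {
    pr <- data.table::data.table(
      pi = S4Vectors::queryHits(hits), gi = S4Vectors::subjectHits(hits))
    pr[, `:=`(summit = info$summit[pi], strand = info$strand[pi],
              gene_id = g$gene_id[gi], g_start = g$start[gi],
              g_end = g$end[gi], tx_end3 = g$tx_end3[gi],
              utr3_start = g$utr3_start[gi], utr3_end = g$utr3_end[gi])]
    # exon membership per candidate pair
    egr <- GenomicRanges::GRanges(
      genes$genes$chrom[match(genes$exons$gene_id, genes$genes$gene_id)],
      IRanges::IRanges(genes$exons$start, genes$exons$end))
    ehits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(info$chrom,
                             IRanges::IRanges(info$summit, info$summit)),
      egr)
    in_exon_keys <- unique(paste(S4Vectors::queryHits(ehits),
                                 genes$exons$gene_id[S4Vectors::subjectHits(ehits)]))
    pr[, in_exon := paste(pi, gene_id) %in% in_exon_keys]
    pr[, in_gene := summit >= g_start & summit <= g_end]
    pr[, in_utr3 := !is.na(utr3_start) & summit >= utr3_start &
         summit <= utr3_end]
    pr[, downstream := ifelse(strand == "+",
                              summit > tx_end3 & summit <= tx_end3 + distal_window_nt,
                              summit < tx_end3 & summit >= tx_end3 - distal_window_nt)]
    pr[, cat := data.table::fifelse(abs(summit - tx_end3) <= terminal_tol_nt, 1L,
         data.table::fifelse(in_utr3, 2L,
           data.table::fifelse(in_gene & in_exon, 3L,
             data.table::fifelse(in_gene, 4L,
               data.table::fifelse(downstream, 5L, 6L)))))]
    pr <- pr[cat < 6L]
    if (nrow(pr)) {
      pr[, dist3 := abs(summit - tx_end3)]
      data.table::setorder(pr, pi, cat, dist3)
      best <- pr[!duplicated(pi)]
      ann[best$pi, `:=`(gene_id = best$gene_id,
                        region = region_levels[best$cat])]
    }
  }
  # apa_index: order of a gene's PACs in transcript orientation
  ann[, summit := info$summit][, strand := info$strand]
  ann[, apa_index := NA_integer_]
  ann[gene_id != "INTERGENIC",
      apa_index := {
        o <- if (strand[1] == "+") order(summit) else order(-summit)
        r <- integer(.N); r[o] <- seq_len(.N); r
      }, by = gene_id]
  ann[, c("summit", "strand") := NULL]
  ann[]
}

#' Annotate a single PAC summit
#' @param summit,chrom,strand coordinates of one PAC summit.
#' @param genes a [gene_models()] object.
#' @param terminal_tol_nt,distal_window_nt see [annotate_pacs()].
#' @return one-row annotation (pac_id "query").
#' @export
assign_region <- function(summit, chrom, strand, genes,
                          terminal_tol_nt = 25L, distal_window_nt = 5000L) {
  annotate_pacs(data.table::data.table(pac_id = "query", chrom = chrom,
                                       strand = strand, summit = summit),
                genes, terminal_tol_nt, distal_window_nt)
}

#' Per-gene APA statistics
#'
#' Histogram inputs and summary fractions for the "PACs per gene"
#' distribution over annotated (non-intergenic) PACs.
#'
#' @param annotations output of [annotate_pacs()].
#' @return list: \code{per_gene} (gene_id, n_pacs), \code{distribution}
#'   (n_pacs, n_genes), \code{mean_pacs_per_gene}, and \code{frac_ge}
#'   (named vector: fraction of genes with >= 2, 3, 4 PACs).
#' @export
apa_stats <- function(annotations) {
  ann <- data.table::as.data.table(annotations)[gene_id != "INTERGENIC"]
  per_gene <- ann[, .(n_pacs = .N), by = gene_id]
  dist <- per_gene[, .(n_genes = .N), by = n_pacs][order(n_pacs)]
  list(per_gene = per_gene,
       distribution = dist,
       mean_pacs_per_gene = mean(per_gene$n_pacs),
       frac_ge = vapply(2:4, function(k) mean(per_gene$n_pacs >= k),
                        numeric(1)) |> setNames(paste0("ge", 2:4)))
}

#' Genes with at least \code{min_pas} annotated PACs
#' @param annotations output of [annotate_pacs()].
#' @param min_pas minimum number of PACs (default 2).
#' @return character vector of gene ids.
#' @export
multi_apa_gene_set <- function(annotations, min_pas = 2L) {
  st <- apa_stats(annotations)
  st$per_gene[st$per_gene$n_pacs >= min_pas, gene_id]
}
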