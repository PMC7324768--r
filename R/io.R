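#' Write pooled allele-depth records as VCF 4.2
#'
#' One "sample" column per pool, with AD (ref,alt allele depths) and DP fields;
#' mapping quality is carried in INFO/MQ.
#'
#' @param records data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{mq} and per-pool \code{<pool>.alt} / \code{<pool>.dp}
#'   columns.
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_pool_vcf <- function(records, path, chrom_lengths = NULL) {
  pools <- pool_names(records)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tetramap")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  hdr <- c(hdr,
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t"))
  cols <- lapply(pools, function(p) {
    alt <- records[[paste0(p, ".alt")]]
    dp <- records[[paste0(p, ".dp")]]
    sprintf("%d,%d:%d", dp - alt, alt, dp)
  })
  body <- do.call(paste, c(list(
    records$chrom, records$pos, ".", records$ref, records$alt, ".", "PASS",
    sprintf("MQ=%g", records$mq), "AD:DP"), cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pooled VCF into the package's record table
#'
#' Parses a VCF 4.2 file whose per-pool genotype columns carry AD and DP,
#' yielding the flat record table used by the filtering and QTL-seq stages.
#' Multiallelic records and records without AD are rejected with the offending
#' position named.
#'
#' @param path VCF path (plain text; CRLF line endings tolerated).
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{mq} and \code{<pool>.alt} / \code{<pool>.dp} per pool.
#' @export
read_pool_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_chunk <- readChar(path, min(file.size(path), 4096), useBytes = TRUE)
  if (grepl("\r", head_chunk, fixed = TRUE)) {
    lines <- sub("\r$", "", readLines(path))
    path <- tempfile(fileext = ".vcf")
    on.exit(unlink(path))
    writeLines(lines, path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic record at ", fix[which(grepl(",", fix[, "ALT"]))[1], "POS"])
  fmt <- v@gt[, "FORMAT"]
  bad <- !grepl("AD", fmt)
  if (any(bad)) stop("record at position ", fix[which(bad)[1], "POS"],
                     " lacks an AD field")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.eE+-]+).*", "\\1",
                                        fix[, "INFO"])))
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"], mq = mq,
                    stringsAsFactors = FALSE)
  alt_mat <- vcfR::masplit(ad, record = 2, sort = FALSE)
  for (p in colnames(ad)) {
    out[[paste0(p, ".alt")]] <- as.integer(alt_mat[, p])
    out[[paste0(p, ".dp")]] <- as.integer(dp[, p])
  }
  rownames(out) <- NULL
  out
}

#' Pool names present in a record table
#' @param records Record table with \code{<pool>.alt}/\code{<pool>.dp} columns.
#' @return Character vector of pool names.
#' @export
pool_names <- function(records) {
  alt <- sub("\\.alt$", "", grep("\\.alt$", names(records), value = TRUE))
  dp <- sub("\\.dp$", "", grep("\\.dp$", names(records), value = TRUE))
  intersect(alt, dp)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features; CDS features point at the gene's single
#' transcript \code{<gene>.t1}.
#'
#' @param genes List of \code{\link{gene_model}} objects.
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for sequence-region pragmas.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path, chrom_lengths = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(chrom_lengths))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(chrom_lengths), as.integer(chrom_lengths)))
  for (g in genes) {
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\ttetramap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\ttetramap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, tid, g$gene_id),
      sprintf("%s\ttetramap\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$chrom, g$segments$start, g$segments$end, g$strand, tid, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3 and a CDS FASTA
#'
#' @param gff_path GFF3 with gene/mRNA/CDS features.
#' @param cds_fasta_path FASTA of CDS sequences named by gene id (optional).
#' @return List of \code{\link{gene_model}} objects.
#' @export
read_gene_models <- function(gff_path, cds_fasta_path = NULL) {
  gr <- rtracklayer::import(gff_path)
  seqs <- NULL
  if (!is.null(cds_fasta_path)) {
    ss <- Biostrings::readDNAStringSet(cds_fasta_path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*", "", names(ss))
  }
  df <- as.data.frame(gr)
  tx <- df[df$type == "mRNA", ]
  tx2gene <- stats::setNames(unlist(tx$Parent), tx$ID)
  cds <- df[df$type == "CDS", ]
  cds$gene <- tx2gene[unlist(cds$Parent)]
  lapply(split(cds, cds$gene), function(d) {
    gid <- d$gene[1]
    gene_model(gid, as.character(d$seqnames[1]), as.character(d$strand[1]),
               data.frame(start = d$start, end = d$end),
               cds_seq = if (!is.null(seqs)) unname(seqs[gid]) else NULL)
  })
}

#' Interval coordinate conversions and lengths
#'
#' Regions are held 1-based inclusive in memory and in TSV output; BED output
#' is 0-based half-open. \code{region_length} is end - start + 1.
#'
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive).
#' @param path File path.
#' @return \code{write_regions_bed} returns the path; \code{read_regions_bed}
#'   and the TSV readers return a region data.frame; \code{region_length} a
#'   numeric vector of lengths in bp.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, format(regions$start - 1, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = b[[2]] + 1, end = b[[3]],
             stringsAsFactors = FALSE)
}

#' @rdname write_regions_bed
#' @export
region_length <- function(regions) {
  if (is.data.frame(regions)) regions$end - regions$start + 1
  else regions[2] - regions[1] + 1
}
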