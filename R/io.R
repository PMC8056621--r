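# All on-disk tables are tab-separated with a header row, UTF-8, '.'
# for missing values. Numeric columns are written with "%.17g" so that a
# write -> read round trip is bit-identical. Internal coordinates are
# 0-based half-open; GFF3 input (1-based closed) is converted on read.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- "."
  out
}

write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    if (is.character(out[[j]])) out[[j]][is.na(out[[j]])] <- "."
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = ".")
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = ".",
                                  stringsAsFactors = FALSE))
}

#' Read and write expression matrices
#'
#' TSV with a `gene_id` column followed by one column per line.
#'
#' @param expr Genes x lines numeric matrix.
#' @param path File path.
#' @param reference Optional reference-template tag stored in
#'   `attr(, "reference")`.
#' @return `read_expression()` returns the matrix; `write_expression()`
#'   the path, invisibly.
#' @name expression-io
NULL

#' @rdname expression-io
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname expression-io
#' @export
read_expression <- function(path, reference = NULL) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id")
    stop(sprintf("%s: first column must be 'gene_id'", path),
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop(sprintf("%s: duplicate gene ids (e.g. line %d)", path,
                 which(duplicated(df$gene_id))[1] + 1), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  attr(m, "reference") <- reference
  m
}

#' Read and write RIL genotype matrices
#'
#' TSV with columns `marker_id`, `chrom`, `bp`, then one column of
#' `A`/`B`/`H`/`N` codes per line. Invalid codes and duplicate marker ids
#' are rejected with their line numbers.
#'
#' @param genotypes A `ril_genotypes`.
#' @param path File path.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  df <- cbind(genotypes$markers[, c("marker_id", "chrom", "bp")],
              as.data.frame(t(genotypes$calls), stringsAsFactors = FALSE))
  write_tsv(df, path)
}

#' @rdname genotype-io
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  need <- c("marker_id", "chrom", "bp")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: need columns marker_id, chrom, bp", path),
         call. = FALSE)
  if (anyDuplicated(df$marker_id))
    stop(sprintf("%s: duplicate marker id at line %d", path,
                 which(duplicated(df$marker_id))[1] + 1), call. = FALSE)
  line_cols <- setdiff(names(df), need)
  calls <- t(as.matrix(df[, line_cols, drop = FALSE]))
  calls[is.na(calls)] <- "N"
  ok <- matrix(calls %in% c("A", "B", "H", "N"), nrow(calls))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: invalid genotype code '%s' at file line %d", path,
                 calls[idx[1], idx[2]], idx[2] + 1), call. = FALSE)
  }
  colnames(calls) <- df$marker_id
  ril_genotypes(calls, df[, need])
}

#' Read and write genetic maps
#'
#' TSV: `marker_id`, `chrom`, `bp`, `cm`.
#' @param map A `genetic_map`.
#' @param path File path.
#' @name map-io
NULL

#' @rdname map-io
#' @export
write_map <- function(map, path) write_tsv(map, path)

#' @rdname map-io
#' @export
read_map <- function(path) validate_genetic_map(read_tsv(path))

#' Write and read gene panels (BED12 + SNP-count TSV)
#'
#' The BED12 file stores the gene span (0-based half-open), UTR extent
#' via the thick region (UTR length = thickStart - chromStart) and the
#' exon structure as `n_junctions + 1` blocks whose sizes sum to the
#' total exon length. The companion TSV stores `gene_id`, `exon_bp`,
#' `snp_count` (and `sj_frac` for simulated panels).
#'
#' @param panel A `gene_panel`.
#' @param bed_path,snp_path File paths.
#' @name panel-io
NULL

#' @rdname panel-io
#' @export
write_panel <- function(panel, bed_path, snp_path) {
  stopifnot(inherits(panel, "gene_panel"))
  n <- nrow(panel)
  bed <- character(n)
  for (i in seq_len(n)) {
    nb <- panel$n_junctions[i] + 1L
    sizes <- diff(round(seq(0, panel$exon_bp[i], length.out = nb + 1)))
    span <- panel$end[i] - panel$start[i]
    gap_total <- span - panel$exon_bp[i]
    gaps <- diff(round(seq(0, gap_total, length.out = nb)))
    starts <- cumsum(c(0, sizes[-nb] + gaps))
    bed[i] <- paste(
      paste0("chr", panel$chrom[i]), panel$start[i], panel$end[i],
      panel$gene_id[i], 0, ".",
      panel$start[i] + panel$utr_bp[i], panel$end[i], 0, nb,
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(starts, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(bed, bed_path)
  snp <- panel[, intersect(c("gene_id", "exon_bp", "snp_count", "sj_frac"),
                           names(panel))]
  write_tsv(snp, snp_path)
  invisible(bed_path)
}

parse_bed12 <- function(bed_path) {
  ln <- readLines(bed_path)
  ln <- ln[!startsWith(ln, "track") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12))
    stop(sprintf("%s: line %d has %d fields; BED12 required", bed_path,
                 which(nf < 12)[1], min(nf)), call. = FALSE)
  df <- data.frame(
    gene_id = vapply(f, `[`, "", 4),
    chrom = as.integer(sub("^chr", "", vapply(f, `[`, "", 1))),
    start = as.integer(vapply(f, `[`, "", 2)),
    end = as.integer(vapply(f, `[`, "", 3)),
    thick_start = as.integer(vapply(f, `[`, "", 7)),
    n_blocks = as.integer(vapply(f, `[`, "", 10)),
    stringsAsFactors = FALSE)
  sizes <- lapply(f, function(x)
    as.integer(strsplit(x[11], ",", fixed = TRUE)[[1]]))
  starts <- lapply(f, function(x)
    as.integer(strsplit(x[12], ",", fixed = TRUE)[[1]]))
  if (any(df$start < 0) || any(df$end <= df$start))
    stop(sprintf("%s: coordinate violation at line %d", bed_path,
                 which(df$end <= df$start | df$start < 0)[1]),
         call. = FALSE)
  df$exon_bp <- vapply(sizes, sum, integer(1))
  df$utr_bp <- df$thick_start - df$start
  df$n_junctions <- df$n_blocks - 1L
  attr(df, "blocks") <- Map(function(d, s, st) {
    data.frame(start = d + st, end = d + st + s)
  }, df$start, sizes, starts)
  df
}

#' @rdname panel-io
#' @export
read_panel <- function(bed_path, snp_path) {
  bed <- parse_bed12(bed_path)
  snp <- read_tsv(snp_path)
  if (anyDuplicated(snp$gene_id))
    stop(sprintf("%s: duplicate gene id at line %d", snp_path,
                 which(duplicated(snp$gene_id))[1] + 1), call. = FALSE)
  m <- merge(bed[, c("gene_id", "chrom", "start", "end", "exon_bp",
                     "utr_bp", "n_junctions")],
             snp[, setdiff(names(snp), "exon_bp")], by = "gene_id")
  m <- m[order(match(m$gene_id, bed$gene_id)), , drop = FALSE]
  if (!"sj_frac" %in% names(m)) m$sj_frac <- NA_real_
  m$snps_per_kb_exon <- 1000 * m$snp_count / m$exon_bp
  rownames(m) <- NULL
  class(m) <- c("gene_panel", "data.frame")
  attr(m, "blocks") <- attr(bed, "blocks")
  m
}

#' Read a gene annotation (BED12 or GFF3) into a gene panel
#'
#' GFF3 coordinates (1-based closed) are converted to the internal
#' 0-based half-open convention; exon lengths are summed per gene, UTR
#' length is the summed width of `five_prime_UTR`/`three_prime_UTR`
#' features, and the junction count is the exon count minus one. GFF3
#' reading uses rtracklayer. SNP counts are not part of the annotation;
#' join them with [read_snp_table()] or [count_exonic_snps()].
#'
#' @param path Annotation file (`.bed` or `.gff3`/`.gff`).
#' @return A `gene_panel` (with `snp_count` NA) carrying an exon-interval
#'   attribute `blocks` used for SNP intersection.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- parse_bed12(path)
    out <- bed[, c("gene_id", "chrom", "start", "end", "exon_bp",
                   "utr_bp", "n_junctions")]
    out$sj_frac <- NA_real_
    out$snp_count <- NA_integer_
    out$snps_per_kb_exon <- NA_real_
    class(out) <- c("gene_panel", "data.frame")
    attr(out, "blocks") <- attr(bed, "blocks")
    return(out)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  get_parent <- function(d) {
    p <- if ("Parent" %in% names(d)) as.character(d$Parent) else d$ID
    sub("^(gene|transcript):", "", p)
  }
  exons <- df[df$type == "exon", , drop = FALSE]
  utrs <- df[df$type %in% c("five_prime_UTR", "three_prime_UTR"), ,
             drop = FALSE]
  ids <- if ("ID" %in% names(genes)) sub("^gene:", "", genes$ID) else
    genes$Name
  blocks <- vector("list", nrow(genes))
  out <- data.frame(gene_id = ids,
                    chrom = as.integer(sub("^chr", "",
                                           as.character(genes$seqnames))),
                    start = genes$start - 1L, end = genes$end,
                    stringsAsFactors = FALSE)
  ex_par <- get_parent(exons); utr_par <- get_parent(utrs)
  out$exon_bp <- vapply(ids, function(i)
    sum(exons$width[ex_par == i]), numeric(1))
  out$utr_bp <- vapply(ids, function(i)
    sum(utrs$width[utr_par == i]), numeric(1))
  out$n_junctions <- vapply(ids, function(i)
    max(0L, sum(ex_par == i) - 1L), integer(1))
  for (i in seq_along(ids))
    blocks[[i]] <- data.frame(start = exons$start[ex_par == ids[i]] - 1L,
                              end = exons$end[ex_par == ids[i]])
  out$sj_frac <- NA_real_
  out$snp_count <- NA_integer_
  out$snps_per_kb_exon <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("gene_panel", "data.frame")
  attr(out, "blocks") <- blocks
  out
}

#' Per-gene exonic SNP counts
#'
#' `read_snp_table()` reads a TSV of `gene_id`, `exon_bp`, `snp_count`.
#' `count_exonic_snps()` counts VCF sites falling inside a panel's exon
#' intervals (VCF positions are 1-based; a site at POS `p` hits an exon
#' block `[start, end)` when `p - 1` is inside it). VCF parsing uses
#' vcfR.
#'
#' @param path TSV or VCF path.
#' @param panel A `gene_panel` carrying exon `blocks` (from
#'   [read_annotation()] or [read_panel()]).
#' @return `read_snp_table()`: the TSV as a data.frame with
#'   `snps_per_kb_exon` added. `count_exonic_snps()`: integer vector of
#'   exonic SNP counts, one per panel gene.
#' @name snp-io
NULL

#' @rdname snp-io
#' @export
read_snp_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "exon_bp", "snp_count")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: need columns gene_id, exon_bp, snp_count", path),
         call. = FALSE)
  df$snps_per_kb_exon <- 1000 * df$snp_count / df$exon_bp
  df
}

#' @rdname snp-io
#' @export
count_exonic_snps <- function(path, panel) {
  blocks <- attr(panel, "blocks")
  if (is.null(blocks))
    stop("panel carries no exon blocks; read it with read_annotation()",
         call. = FALSE)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  chrom <- as.integer(sub("^chr", "", vcfR::getCHROM(v)))
  pos0 <- vcfR::getPOS(v) - 1L
  vapply(seq_len(nrow(panel)), function(i) {
    b <- blocks[[i]]
    onchr <- chrom == panel$chrom[i]
    if (!any(onchr)) return(0L)
    p <- pos0[onchr]
    sum(vapply(p, function(x) any(x >= b$start & x < b$end), logical(1)))
  }, integer(1))
}

#' Write eQTL records, bias reports and window profiles
#'
#' @param records An `eqtl_records` data.frame.
#' @param report Any of the report objects (`bias_summary`,
#'   `reference_discordance`, `criteria_comparison`, `ratio_tests`,
#'   `divergence_fit`).
#' @param profile A `window_profile`.
#' @param path Output path.
#' @name report-io
NULL

#' @rdname report-io
#' @export
write_records <- function(records, path) write_tsv(records, path)

#' @rdname report-io
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname report-io
#' @export
write_windows_bed <- function(profile, path) {
  w <- profile$windows
  w <- w[w$n_genes > 0, , drop = FALSE]
  lines <- sprintf("chr%s\t%d\t%d\twin\t%.4f", w$chrom, as.integer(w$start),
                   as.integer(w$end), w$prop_parent1)
  writeLines(lines, path)
  invisible(path)
}
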