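# Gene panel (ASD/IDD membership + exon models) and fetal brain CRE intervals.

#' Read the gene panel and regulatory-element intervals
#'
#' @param panel_path TSV with header columns `gene_symbol, is_asd_idd,
#'   sfari_score, pli, exons`; `exons` is a semicolon-separated list of
#'   `chrom:start-end` 1-based closed intervals.
#' @param cre_bed_path 4+ column BED (0-based half-open) of fetal
#'   brain-specific cis-regulatory elements, linked gene symbol in column 4.
#' @return list with `panel` (data.frame, gene symbols unique), `exons`
#'   (GRanges of panel exons, metadata `gene_symbol`, `is_asd_idd`) and `cre`
#'   (GRanges with metadata `linked_gene`; 1-based closed after import).
#' @export
read_panel_and_intervals <- function(panel_path, cre_bed_path) {
  panel <- read_tsv(panel_path)
  need <- c("gene_symbol", "is_asd_idd", "sfari_score", "pli", "exons")
  if (length(setdiff(need, names(panel))))
    trioppv_stop("panel table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(panel$gene_symbol))
    trioppv_stop("duplicate gene symbol in panel: ",
                 panel$gene_symbol[duplicated(panel$gene_symbol)][1])
  panel$is_asd_idd <- as.logical(panel$is_asd_idd) |
    panel$is_asd_idd %in% c(1, "1", "yes", "TRUE")

  ex <- .parse_exons(panel)
  no_ex <- panel$is_asd_idd & !(panel$gene_symbol %in% unique(ex$gene_symbol))
  if (any(no_ex))
    trioppv_stop("ASD/IDD panel gene without exon intervals: ",
                 paste(panel$gene_symbol[no_ex], collapse = ", "))
  exons <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end),
    gene_symbol = ex$gene_symbol,
    is_asd_idd = panel$is_asd_idd[match(ex$gene_symbol, panel$gene_symbol)])

  cre <- .read_cre_bed(cre_bed_path)
  list(panel = panel, exons = exons, cre = cre)
}

.parse_exons <- function(panel) {
  pieces <- lapply(seq_len(nrow(panel)), function(i) {
    s <- panel$exons[i]
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
    bad <- lengths(m) != 4
    if (any(bad))
      trioppv_stop("malformed exon interval for ", panel$gene_symbol[i],
                   ": ", parts[bad][1])
    data.frame(gene_symbol = panel$gene_symbol[i],
               chrom = vapply(m, `[`, "", 2),
               start = as.numeric(vapply(m, `[`, "", 3)),
               end = as.numeric(vapply(m, `[`, "", 4)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(gene_symbol = character(), chrom = character(),
                      start = numeric(), end = numeric())
  if (any(out$start > out$end))
    trioppv_stop("exon interval with start > end in panel")
  out
}

.read_cre_bed <- function(path) {
  if (!file.exists(path)) trioppv_stop("CRE BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(GenomicRanges::GRanges(linked_gene = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4))
    trioppv_stop("CRE BED requires 4+ columns (linked gene in column 4)")
  start0 <- as.numeric(vapply(fields, `[`, "", 2))
  end0 <- as.numeric(vapply(fields, `[`, "", 3))
  bad <- which(start0 >= end0)
  if (length(bad))
    trioppv_stop("CRE BED line ", bad[1], ": start >= end")
  # rtracklayer performs the 0-based half-open -> 1-based closed conversion
  gr <- rtracklayer::import(path, format = "BED")
  gr$linked_gene <- gr$name
  gr$name <- NULL
  gr
}
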