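# Structural-variant engine: CNV calling from log2-ratio segments, dual-caller
# consensus, pooling, trio inheritance, rarity and exonic panel overlap.

.empty_sv_calls <- function(samples = character(0)) {
  structure(list(
    calls = data.frame(caller = character(), sv_type = character(),
                       chrom = character(), start = numeric(),
                       end = numeric(), chrom2 = character(),
                       pos2 = numeric(), filter_pass = logical(),
                       precise = logical(), maf = numeric(),
                       bnd_unresolved = logical(), stringsAsFactors = FALSE),
    geno = matrix(character(0), 0, length(samples),
                  dimnames = list(NULL, samples))),
    class = "sv_calls")
}

#' Call copy-number variants from log2-ratio segments
#'
#' Segments at or below `log2_del` (default -0.6) become deletions, at or
#' above `log2_dup` (default 0.4) duplications (both boundaries inclusive).
#' Adjacent same-type segments of one sample closer than `merge_gap` are
#' merged. The carrier genotype is heterozygous unless the log2 ratio crosses
#' the homozygous bounds (`log2_del_hom`, `log2_dup_hom`); other samples are
#' genotyped by reciprocal overlap (>= `recip_overlap_min`) of their own
#' qualifying segments, reference otherwise.
#'
#' @param segments data.frame from [read_cnv_segments()].
#' @param samples sample universe for the genotype matrix (defaults to the
#'   samples present in `segments`).
#' @param config [trioppv_config()].
#' @return an `sv_calls` object with `caller = "cnv"`; one call per distinct
#'   locus (carrier calls matching across samples are collapsed).
#' @export
cnv_from_log2 <- function(segments, samples = NULL,
                          config = trioppv_config()) {
  config <- as_trioppv_config(config)
  if (is.null(samples)) samples <- sort(unique(segments$sample_id))
  sv_type <- ifelse(segments$log2 <= config$log2_del, "DEL",
                    ifelse(segments$log2 >= config$log2_dup, "DUP", NA))
  seg <- segments[!is.na(sv_type), , drop = FALSE]
  seg$sv_type <- sv_type[!is.na(sv_type)]
  if (nrow(seg) == 0) return(.empty_sv_calls(samples))

  # merge adjacent same-type segments per sample/chrom
  merged <- list()
  for (key in unique(paste(seg$sample_id, seg$chrom, seg$sv_type))) {
    s <- seg[paste(seg$sample_id, seg$chrom, seg$sv_type) == key, ,
             drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cur <- s[1, ]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] - cur$end <= config$merge_gap) {
        cur$end <- max(cur$end, s$end[i])
        cur$log2 <- min(cur$log2, s$log2[i])  # most extreme ratio wins
        if (cur$sv_type == "DUP") cur$log2 <- max(cur$log2, s$log2[i])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- s[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
  }
  m <- do.call(rbind, merged)
  hom <- (m$sv_type == "DEL" & m$log2 <= config$log2_del_hom) |
         (m$sv_type == "DUP" & m$log2 >= config$log2_dup_hom)
  m$gt <- ifelse(hom, "hom_alt", "het")

  # cluster per-sample calls into loci across samples
  m <- m[order(m$chrom, m$start, m$end, m$sample_id), , drop = FALSE]
  locus <- rep(NA_integer_, nrow(m))
  loci <- list()  # representative intervals
  for (i in seq_len(nrow(m))) {
    hit <- NA_integer_
    for (k in seq_along(loci)) {
      L <- loci[[k]]
      if (L$sv_type == m$sv_type[i] && L$chrom == m$chrom[i] &&
          reciprocal_overlap(L$start, L$end, m$start[i], m$end[i]) >=
            config$recip_overlap_min) { hit <- k; break }
    }
    if (is.na(hit)) {
      loci[[length(loci) + 1]] <- list(chrom = m$chrom[i], start = m$start[i],
                                       end = m$end[i], sv_type = m$sv_type[i])
      hit <- length(loci)
    }
    locus[i] <- hit
  }
  calls <- do.call(rbind, lapply(seq_along(loci), function(k) {
    rows <- m[locus == k, , drop = FALSE]
    data.frame(caller = "cnv", sv_type = rows$sv_type[1],
               chrom = rows$chrom[1], start = min(rows$start),
               end = max(rows$end), chrom2 = NA_character_, pos2 = NA_real_,
               filter_pass = TRUE, precise = TRUE, maf = NA_real_,
               bnd_unresolved = FALSE, stringsAsFactors = FALSE)
  }))
  geno <- matrix("hom_ref", nrow(calls), length(samples),
                 dimnames = list(NULL, samples))
  for (i in seq_len(nrow(m))) {
    j <- match(m$sample_id[i], samples)
    if (!is.na(j)) geno[locus[i], j] <- m$gt[i]
  }
  structure(list(calls = calls, geno = geno), class = "sv_calls")
}

#' Consensus intersection of two SV call sets
#'
#' Set A is gated on FILTER PASS, set B on FILTER PASS and the PRECISE flag,
#' then mutual calls are extracted: two calls match iff they share sv type and
#' chromosome and either their reciprocal overlap is at least
#' `recip_overlap_min` (DEL/DUP/INV) or their breakends lie within
#' `breakend_tol_bp` (INS/TRA). Matching is one-to-one and greedy by
#' descending overlap (ascending distance for breakend types), ties broken by
#' leftmost start. Merged coordinates are the interval union; trio genotypes
#' are taken from the set-A record.
#'
#' @param set_a,set_b `sv_calls` objects (A is the primary caller).
#' @param config [trioppv_config()].
#' @return an `sv_calls` object with `caller = "consensus"` and provenance
#'   columns `a_index`, `b_index` into the gated inputs.
#' @export
consensus_intersect <- function(set_a, set_b, config = trioppv_config()) {
  config <- as_trioppv_config(config)
  a_keep <- which(set_a$calls$filter_pass)
  b_keep <- which(set_b$calls$filter_pass & set_b$calls$precise)
  a <- set_a$calls[a_keep, , drop = FALSE]
  b <- set_b$calls[b_keep, , drop = FALSE]
  out <- .empty_sv_calls(colnames(set_a$geno))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)

  cand <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$sv_type[i] != b$sv_type[j] || a$chrom[i] != b$chrom[j]) next
    if (a$sv_type[i] %in% c("INS", "TRA")) {
      d <- abs(a$start[i] - b$start[j])
      if (d > config$breakend_tol_bp) next
      score <- -d
    } else {
      ro <- reciprocal_overlap(a$start[i], a$end[i], b$start[j], b$end[j])
      if (ro < config$recip_overlap_min) next
      score <- ro
    }
    cand[[length(cand) + 1]] <- data.frame(i = i, j = j, score = score)
  }
  if (!length(cand)) return(out)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, a$start[cand$i], b$start[cand$j]), ,
               drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pick <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$i[k]] && !used_b[cand$j[k]]) {
      pick[k] <- TRUE
      used_a[cand$i[k]] <- TRUE
      used_b[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[pick, , drop = FALSE]
  if (!nrow(cand)) return(out)
  calls <- data.frame(
    caller = "consensus", sv_type = a$sv_type[cand$i], chrom = a$chrom[cand$i],
    start = pmin(a$start[cand$i], b$start[cand$j]),
    end = pmax(a$end[cand$i], b$end[cand$j]),
    chrom2 = a$chrom2[cand$i], pos2 = a$pos2[cand$i],
    filter_pass = TRUE, precise = TRUE,
    maf = pmax(ifelse(is.na(a$maf[cand$i]), -1, a$maf[cand$i]),
               ifelse(is.na(b$maf[cand$j]), -1, b$maf[cand$j])),
    bnd_unresolved = a$bnd_unresolved[cand$i],
    a_index = a_keep[cand$i], b_index = b_keep[cand$j],
    stringsAsFactors = FALSE)
  calls$maf[calls$maf < 0] <- NA_real_
  ord <- order(calls$chrom, calls$start, calls$end)
  structure(list(calls = calls[ord, , drop = FALSE],
                 geno = set_a$geno[calls$a_index[ord], , drop = FALSE]),
            class = "sv_calls")
}

#' Pool consensus and CNV call sets, deduplicated
#'
#' Combines the dual-caller consensus calls with CNV log2-ratio calls,
#' dropping any CNV call that matches a consensus call under the same
#' criterion used for consensus matching (the consensus record, which carries
#' breakpoint-level coordinates, wins).
#'
#' @param consensus,cnv `sv_calls` objects.
#' @param config [trioppv_config()].
#' @return pooled `sv_calls` object; genotype matrices are aligned on the
#'   union of samples (samples absent from one set are reference).
#' @export
pool_sv_calls <- function(consensus, cnv, config = trioppv_config()) {
  config <- as_trioppv_config(config)
  keep <- rep(TRUE, nrow(cnv$calls))
  for (i in seq_len(nrow(cnv$calls))) {
    for (j in seq_len(nrow(consensus$calls))) {
      if (cnv$calls$sv_type[i] == consensus$calls$sv_type[j] &&
          cnv$calls$chrom[i] == consensus$calls$chrom[j] &&
          reciprocal_overlap(cnv$calls$start[i], cnv$calls$end[i],
                             consensus$calls$start[j],
                             consensus$calls$end[j]) >=
            config$recip_overlap_min) { keep[i] <- FALSE; break }
    }
  }
  samples <- union(colnames(consensus$geno), colnames(cnv$geno))
  align <- function(g) {
    out <- matrix("hom_ref", nrow(g), length(samples),
                  dimnames = list(NULL, samples))
    if (ncol(g)) out[, colnames(g)] <- g
    out
  }
  common <- intersect(names(consensus$calls), names(cnv$calls))
  calls <- rbind(consensus$calls[, common, drop = FALSE],
                 cnv$calls[keep, common, drop = FALSE])
  geno <- rbind(align(consensus$geno), align(cnv$geno)[keep, , drop = FALSE])
  rownames(calls) <- NULL
  structure(list(calls = calls, geno = geno), class = "sv_calls")
}

#' Classify trio inheritance of SV calls
#'
#' Same label logic as small variants, without a DQ gate: a carrier child with
#' both parents reference is `de_novo`; a homozygous-alternate child with two
#' heterozygous parents is `homozygous_recessive`; a hemizygous (non-PAR chrX,
#' male proband) carrier child with a carrier mother is `hemizygous_maternal`;
#' single-parent transmission gives `inherited_maternal` / `inherited_paternal`;
#' otherwise `inherited_biparental` / `uninformative`. Calls where the child
#' is reference are not emitted.
#'
#' @param svset `sv_calls` object.
#' @param pedigree pedigree data.frame ([read_pedigree()]).
#' @param config [trioppv_config()].
#' @return data.frame with one row per (call, trio) where the child carries
#'   the variant: `call_index`, `family_id`, `label`, plus the call columns
#'   and `n_carrier_families` (families with any carrier, for the singleton
#'   rule).
#' @export
classify_sv_inheritance <- function(svset, pedigree,
                                    config = trioppv_config()) {
  config <- as_trioppv_config(config)
  trios <- trio_members(pedigree)
  calls <- svset$calls
  geno <- svset$geno
  empty <- cbind(data.frame(call_index = integer(), family_id = character(),
                            label = character(),
                            n_carrier_families = integer()),
                 calls[0, , drop = FALSE])
  if (nrow(calls) == 0 || nrow(trios) == 0) return(empty)
  carrier <- function(g) g %in% c("het", "hom_alt", "hemi_alt")

  # families carrying each call (for the cohort-singleton rule)
  fam_carrier <- matrix(FALSE, nrow(calls), nrow(trios))
  for (t in seq_len(nrow(trios))) {
    ids <- c(trios$proband[t], trios$mother[t], trios$father[t])
    ids <- intersect(ids, colnames(geno))
    if (length(ids))
      fam_carrier[, t] <- apply(geno[, ids, drop = FALSE], 1,
                                function(g) any(carrier(g)))
  }
  n_carrier_families <- rowSums(fam_carrier)

  par <- config$par_intervals
  pieces <- list()
  for (t in seq_len(nrow(trios))) {
    gc <- geno[, trios$proband[t]]
    rows <- which(carrier(gc))
    if (!length(rows)) next
    gm <- geno[rows, trios$mother[t]]
    gf <- geno[rows, trios$father[t]]
    gc <- gc[rows]
    is_x <- calls$chrom[rows] %in% c("chrX", "X")
    in_par <- rep(FALSE, length(rows))
    for (k in seq_len(nrow(par)))
      in_par <- in_par | (is_x & calls$start[rows] >= par$start[k] &
                            calls$start[rows] <= par$end[k])
    hemi_ctx <- is_x & !in_par & trios$proband_sex[t] == "male"

    cm <- carrier(gm); cf <- carrier(gf)
    rm_ <- gm %in% c("hom_ref", "hemi_ref")
    rf <- gf %in% c("hom_ref", "hemi_ref")
    lab <- rep("uninformative", length(rows))
    lab[!hemi_ctx & rm_ & rf] <- "de_novo"
    lab[!hemi_ctx & gc == "hom_alt" & gm == "het" & gf == "het"] <-
      "homozygous_recessive"
    plain <- !hemi_ctx & lab == "uninformative"
    lab[plain & cm & !cf & rf] <- "inherited_maternal"
    lab[plain & cf & !cm & rm_] <- "inherited_paternal"
    lab[!hemi_ctx & lab == "uninformative" & cm & cf] <- "inherited_biparental"
    lab[hemi_ctx & cm] <- "hemizygous_maternal"
    lab[hemi_ctx & !cm & rm_ & rf] <- "de_novo"
    pieces[[length(pieces) + 1]] <- cbind(
      data.frame(call_index = rows, family_id = trios$family_id[t],
                 label = lab,
                 n_carrier_families = n_carrier_families[rows],
                 stringsAsFactors = FALSE),
      calls[rows, , drop = FALSE])
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' SV rarity filter
#'
#' Homozygous-recessive SVs pass below MAF 0.2; all other labels must be below
#' MAF 0.01 AND be cohort singletons (carried by exactly one family). A
#' missing MAF counts as 0.
#'
#' @param label SV inheritance labels.
#' @param maf population frequencies (NA treated as 0).
#' @param n_carrier_families number of carrier families per call.
#' @param config [trioppv_config()].
#' @return logical pass vector.
#' @export
sv_rarity_filter <- function(label, maf, n_carrier_families,
                             config = trioppv_config()) {
  config <- as_trioppv_config(config)
  maf0 <- ifelse(is.na(maf), 0, maf)
  ifelse(label == "homozygous_recessive",
         maf0 < config$sv_maf_hom,
         maf0 < config$sv_maf & n_carrier_families == 1)
}

#' Panel genes whose exons an SV overlaps
#'
#' Intersects each SV interval (breakend points for INS/TRA, including the
#' mate breakend when resolved) with the exon models of ASD/IDD panel genes;
#' a single overlapping base qualifies.
#'
#' @param calls data.frame with `sv_type, chrom, start, end, chrom2, pos2`.
#' @param panel_exons GRanges of panel exons from [read_panel_and_intervals()]
#'   (`gene_symbol`, `is_asd_idd` metadata).
#' @return list (one element per call) of sorted gene-symbol vectors.
#' @export
exonic_gene_overlap <- function(calls, panel_exons) {
  ex <- panel_exons[panel_exons$is_asd_idd]
  n <- nrow(calls)
  if (n == 0 || length(ex) == 0) return(rep(list(character(0)), n))
  point <- calls$sv_type %in% c("INS", "TRA")
  qstart <- ifelse(point, calls$start, calls$start)
  qend <- ifelse(point, calls$start, calls$end)
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(qstart, qend))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, ex))
  res <- rep(list(character(0)), n)
  if (length(hits)) {
    sp <- split(ex$gene_symbol[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) res[[as.integer(q)]] <- sort(unique(sp[[q]]))
  }
  # mate breakends of resolved translocations
  tra <- which(calls$sv_type == "TRA" & !is.na(calls$chrom2))
  if (length(tra)) {
    gr2 <- GenomicRanges::GRanges(calls$chrom2[tra],
                                  IRanges::IRanges(calls$pos2[tra],
                                                   calls$pos2[tra]))
    hits2 <- suppressWarnings(GenomicRanges::findOverlaps(gr2, ex))
    if (length(hits2)) {
      sp2 <- split(ex$gene_symbol[S4Vectors::subjectHits(hits2)],
                   S4Vectors::queryHits(hits2))
      for (q in names(sp2)) {
        i <- tra[as.integer(q)]
        res[[i]] <- sort(unique(c(res[[i]], sp2[[q]])))
      }
    }
  }
  res
}
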