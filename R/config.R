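#' Pipeline configuration
#'
#' Returns the full set of tunable thresholds used by the prioritization
#' pipeline, with defaults matching the published decision rules: VQSR-pass
#' bi-allelic sites with depth >= 10 in all trio members; heterozygous SNVs at
#' GQ >= 99 and 0.3 <= AF < 0.8, heterozygous INDELs at GQ >= 90, homozygous
#' calls at GQ >= 25 and AF >= 0.8; de novo candidates at DQ >= 7 with
#' MAF < 0.001 and cohort allele count 1; inherited variants at MAF < 0.01;
#' CNV log2-ratio cutoffs -0.6 (deletion) and 0.4 (duplication); SV consensus
#' at reciprocal overlap >= 0.5 (500 bp breakend tolerance); homozygous-
#' recessive SVs at MAF < 0.2, other SVs at MAF < 0.01 and cohort-singleton;
#' mitochondrial reporting above 5% heteroplasmy; repeat outliers at z > 10.
#'
#' @param ... named overrides of any default listed above, e.g.
#'   `trioppv_config(dq_threshold = 5)`.
#' @return a named list of class `trioppv_config`.
#' @examples
#' cfg <- trioppv_config(maf_denovo = 0.005)
#' cfg$dq_threshold
#' @export
trioppv_config <- function(...) {
  cfg <- list(
    # small-variant QC
    min_depth      = 10,
    gq_het_snv     = 99,
    gq_het_indel   = 90,
    gq_hom         = 25,
    af_het_low     = 0.3,
    af_het_high    = 0.8,   # right-open: AF < 0.8
    af_hom_min     = 0.8,
    # de novo scoring
    dq_threshold   = 7,
    mu             = 1e-8,
    p_floor        = 1e-4,  # population frequency prior = max(MAF, p_floor)
    # rarity
    maf_denovo     = 0.001,
    maf_inherited  = 0.01,
    # splice
    spliceai_min   = 0.5,   # strict >
    # compound-het / hemizygous MPC gates (strict >)
    mpc_single     = 2,
    mpc_pair       = 1,
    # chrX pseudoautosomal regions (hg38), treated as autosomal
    par_intervals  = data.frame(start = c(10001, 155701383),
                                end   = c(2781479, 156030895)),
    # SV engine
    recip_overlap_min = 0.5,
    breakend_tol_bp   = 500,
    log2_del          = -0.6,
    log2_dup          = 0.4,
    log2_del_hom      = -1.5,  # below this a CNV deletion is called homozygous
    log2_dup_hom      = 0.85,
    merge_gap         = 1000,
    sv_maf_hom        = 0.2,
    sv_maf            = 0.01,
    # mitochondria
    mito_heteroplasmy_pct = 5,
    # repeats
    str_z_threshold = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      trioppv_stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "trioppv_config")
}

as_trioppv_config <- function(config) {
  if (inherits(config, "trioppv_config")) return(config)
  if (is.list(config)) return(do.call(trioppv_config, config))
  trioppv_stop("config must be a trioppv_config or a named list")
}
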