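#' Run the full analysis pipeline
#'
#' Chains the stages in study order: karyotype classification from binned
#' coverage; subgenome-map inference or validation; variant filtering;
#' diversity statistics; distances, NJ tree, PCoA; pairwise PhiPT and
#' windowed scan; minor-allele cataloguing; admixture classification; and
#' (when expression is supplied) homoeolog dominance. Each stage writes a
#' TSV under \code{out_dir}; a JSON manifest records input MD5 hashes,
#' effective parameters, the post-filter record counts and package
#' version, so every output is reproducible from the manifest. A stage
#' failure aborts with the stage name; outputs written so far are kept
#' with a \code{.partial} marker file. A missing optional input skips its
#' stage with a logged notice.
#'
#' @param coverage_files character vector of binned-coverage TSV paths
#'   (optional)
#' @param vcf path to a multi-sample VCF (optional)
#' @param samples path to the sample metadata TSV (optional; required for
#'   population-level stages)
#' @param q_matrix path to the ancestry Q TSV (optional)
#' @param expression path to the triplet expression TSV (optional)
#' @param out_dir output directory (created if needed)
#' @param reference named vector of sequence lengths (required with
#'   coverage input)
#' @param map a [subgenome_map]; or \code{NULL} to infer one, in which
#'   case \code{diploid_id} and \code{tetraploid_id} must name accessions
#'   among the coverage files
#' @param diploid_id,tetraploid_id accession ids of the ladder
#'   representatives used for map inference
#' @param params named list overriding stage parameters (maf_min,
#'   max_missing, drop_indels, depth_floor, frac_present, ratio_hi,
#'   affinity_min, window_bp, hom_threshold, q_cutoff, alpha, min_tpm,
#'   permutations)
#' @param seed RNG seed for permutation tests
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(coverage_files = NULL, vcf = NULL, samples = NULL,
                         q_matrix = NULL, expression = NULL, out_dir,
                         reference = NULL, map = camelina_subgenome_map(),
                         diploid_id = NULL, tetraploid_id = NULL,
                         params = list(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- utils::modifyList(list(
    maf_min = 0.01, max_missing = 0.20, drop_indels = TRUE,
    depth_floor = 0.25, frac_present = 0.5, ratio_hi = 1.5,
    affinity_min = 0.5, window_bp = 1e6, hom_threshold = 0.05,
    q_cutoff = 0.70, alpha = 0.05, min_tpm = 0.01, permutations = 0),
    params)
  manifest <- list(seed = seed, parameters = p,
                   package_version = as.character(utils::packageVersion("camelpop")),
                   r_version = R.version.string,
                   inputs = list(), stages = list())
  hash_in <- function(paths) if (length(paths))
    as.list(tools::md5sum(unlist(paths))) else list()
  manifest$inputs <- hash_in(c(coverage_files, vcf, samples, q_matrix,
                               expression))
  partial <- file.path(out_dir, ".partial")
  file.create(partial)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  calls <- NULL
  if (!is.null(coverage_files)) {
    stopifnot(!is.null(reference))
    covs <- stage("read_coverage", function()
      lapply(coverage_files, read_coverage, reference_index = reference))
    if (is.null(map)) {
      map <- stage("infer_subgenome_map", function() {
        pres <- lapply(covs, function(cv)
          chromosome_presence(normalize_coverage(cv), p$depth_floor,
                              p$frac_present))
        names(pres) <- vapply(covs, `[[`, "", "accession_id")
        if (is.null(diploid_id) || is.null(tetraploid_id))
          stop("map inference needs diploid_id and tetraploid_id")
        ps <- function(id) {
          pr <- pres[[id]]
          pr$chromosome[pr$present]
        }
        infer_subgenome_map(ps(diploid_id), ps(tetraploid_id),
                            names(reference))
      })
      tsv(as.data.frame(map), "subgenome_map.tsv")
    }
    calls <- stage("classify_karyotype", function()
      lapply(covs, call_karyotype, map = map,
             depth_floor = p$depth_floor, frac_present = p$frac_present,
             ratio_hi = p$ratio_hi, affinity_min = p$affinity_min))
    tab <- do.call(rbind, lapply(calls, function(k)
      data.frame(accession_id = k$accession_id, class = k$class,
                 sg1_fraction = k$affinity$fraction[1],
                 sg2_fraction = k$affinity$fraction[2],
                 sg3_fraction = k$affinity$fraction[3],
                 sg1_sg2_depth_ratio = k$evidence$sg1_sg2_depth_ratio)))
    tsv(tab, "karyotype_calls.tsv")
    manifest$stages$classify_karyotype <-
      list(n_accessions = length(calls), classes = table(tab$class))
  }

  smp <- if (!is.null(samples)) read_samples(samples) else NULL
  if (!is.null(vcf)) {
    gm <- stage("read_vcf", function() read_vcf(vcf)$genotypes)
    gmf <- stage("filter_variants", function()
      filter_variants(gm, p$maf_min, p$max_missing, p$drop_indels))
    manifest$stages$filter_variants <- as.list(attr(gmf, "filter_log"))
    fr <- allele_freqs(gmf)
    div <- data.frame(chromosome = fr$chromosome,
                      subgenome = map$subgenome[match(fr$chromosome,
                                                      map$chromosome)],
                      position = fr$position,
                      he = gene_diversity(fr), pic = pic(fr))
    tsv(div, "diversity.tsv")
    d <- stage("distance", function() nei_da_distance(gmf))
    tr <- stage("nj_tree", function() nj_tree(d))
    write_newick(tr, file.path(out_dir, "nj_tree.nwk"))
    pc <- stage("pcoa", function() pcoa(d))
    tsv(data.frame(sample_id = rownames(pc$points),
                   pc$points[, 1:min(3, ncol(pc$points)), drop = FALSE]),
        "pcoa.tsv")
    tsv(data.frame(axis = seq_along(pc$var_frac),
                   var_frac = pc$var_frac), "pcoa_variance.tsv")
    if (!is.null(smp)) {
      grp <- stats::setNames(smp$group_label, smp$accession_id)
      ok <- names(which(table(grp[gmf$sample_ids]) >= 2))
      keep <- gmf$sample_ids[grp[gmf$sample_ids] %in% ok]
      if (length(ok) >= 2) {
        sub <- genotype_matrix(gmf$variants,
                               gmf$calls[, keep, drop = FALSE], keep)
        fst <- stage("amova_phipt", function()
          amova_phipt(sub, grp[keep], permutations = p$permutations,
                      seed = seed))
        tsv(as.data.frame(fst), "fst_pairwise.tsv")
        scan <- stage("fst_scan", function()
          fst_scan(sub, grp[keep], window_bp = p$window_bp))
        tsv(scan, "fst_scan.tsv")
      } else manifest$stages$amova_phipt <- "skipped: <2 populations"
      spc <- stats::setNames(smp$species_label, smp$accession_id)
      cat3 <- stage("minor_alleles", function()
        minor_allele_catalog(gmf, spc[gmf$sample_ids],
                             hom_threshold = p$hom_threshold))
      tsv(data.frame(group = names(cat3$sets),
                     n_loci = lengths(cat3$sets)), "minor_alleles.tsv")
      if (!is.null(cat3$venn))
        tsv(data.frame(region = names(cat3$venn), count = cat3$venn),
            "minor_allele_venn.tsv")
    }
  }

  if (!is.null(q_matrix)) {
    qm <- stage("classify_admixture", function()
      classify_admixture(read_q_matrix(q_matrix), cutoff = p$q_cutoff))
    tsv(qm, "admixture.tsv")
    manifest$stages$classify_admixture <-
      list(n_assigned = sum(qm$assignment != "ADMIXED"),
           n_admixed = sum(qm$assignment == "ADMIXED"))
  }

  if (!is.null(expression)) {
    dm <- stage("dominance", function()
      dominance_analysis(read_expression(expression), alpha = p$alpha,
                         min_tpm = p$min_tpm))
    tsv(dm$calls, "dominance_calls.tsv")
    tsv(dm$summary, "dominance_summary.tsv")
  } else manifest$stages$dominance <- "skipped: no expression input"

  manifest$stages <- rapply(manifest$stages, unclass, how = "replace")
  jsonlite::write_json(
    manifest[c("seed", "parameters", "package_version", "r_version",
               "inputs", "stages")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  unlink(partial)
  invisible(manifest)
}
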