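# Configuration-driven orchestration: synthetic demo or file inputs,
# stages in dependency order, deterministic outputs, and a run manifest
# with content checksums.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV count table
#'
#' @param path TSV with a header row and columns including `gene_id` and
#'   `count` (or `mirna_id`/`sequence` variants).
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

#' Write a synthetic dataset to a directory
#'
#' Emits `annotation.gtf`, `reads.bed12`, `countsA.tsv`/`countsB.tsv`
#' (count-universe experiment), `gene_countsA.tsv`/`gene_countsB.tsv`
#' (annotation universe), `smallrna.tsv`, `mature.fa`, `gwas.tsv`,
#' `truth.json` and `config.json`, all plain text and byte-deterministic
#' under a fixed seed.
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_annotation(dataset$annotation, p("annotation.gtf"))
  write_alignments_bed12(dataset$alignments, p("reads.bed12"))
  write_tsv(dataset$counts$counts_a, p("countsA.tsv"))
  write_tsv(dataset$counts$counts_b, p("countsB.tsv"))
  if (!is.null(dataset$gene_counts)) {
    write_tsv(dataset$gene_counts$counts_a, p("gene_countsA.tsv"))
    write_tsv(dataset$gene_counts$counts_b, p("gene_countsB.tsv"))
  }
  write_tsv(dataset$smallrna$tags, p("smallrna.tsv"))
  write_fasta(dataset$smallrna$mature_db, p("mature.fa"))
  write_tsv(dataset$gwas, p("gwas.tsv"))
  truth <- dataset$truth
  truth_out <- list(novel_units = truth$novel_units,
                    as_events = truth$as_events,
                    extensions = truth$extensions,
                    de_genes = dataset$counts$truth_de,
                    de_genes_annotation = if (!is.null(dataset$gene_counts))
                      dataset$gene_counts$truth_de else NULL,
                    smallrna_categories = dataset$smallrna$truth)
  jsonlite::write_json(truth_out, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(dataset$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Defaults equal the analysis thresholds of every stage: TAR depth 2,
#' continuous mapping length 150 bp, intergenic margin 200 bp, cluster gap
#' 3 kb, junction support 2 reads / 5 bp overhangs, DE thresholds
#' FDR <= 0.001 and |log2 ratio| >= 1, miRNA thresholds p < 0.01 and
#' |log2 fc| >= 1, GWAS window 2.5 Mb.
#'
#' @param seed RNG seed for synthetic mode.
#' @param outdir output directory.
#' @param synthetic if TRUE, inputs are generated by [generate_dataset()];
#'   otherwise `inputs` must name existing files.
#' @param inputs named list of input paths (`annotation`, `reads`,
#'   `counts_a`, `counts_b`, `smallrna`, `mature`, `gwas`).
#' @param stages named logical vector toggling `tars`, `splicing`,
#'   `boundaries`, `expression`, `smallrna`, `integration`.
#' @param min_depth,min_len,margin,gap,min_junc_reads,min_overhang,fdr_max,min_abs_log2,mirna_p,window
#'   stage thresholds (see above).
#' @param sim_config optional [simulation_config()] overriding the default
#'   built from `seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("tarscribe_run_"),
                            synthetic = TRUE, inputs = list(),
                            stages = c(tars = TRUE, splicing = TRUE,
                                       boundaries = TRUE, expression = TRUE,
                                       smallrna = TRUE, integration = TRUE),
                            min_depth = 2, min_len = 150, margin = 200,
                            gap = 3000, min_junc_reads = 2, min_overhang = 5,
                            fdr_max = 0.001, min_abs_log2 = 1,
                            mirna_p = 0.01, window = 2.5e6,
                            sim_config = NULL) {
  defaults <- c(tars = TRUE, splicing = TRUE, boundaries = TRUE,
                expression = TRUE, smallrna = TRUE, integration = TRUE)
  defaults[names(stages)] <- stages
  structure(list(seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic, inputs = inputs, stages = defaults,
                 min_depth = min_depth, min_len = min_len, margin = margin,
                 gap = gap, min_junc_reads = min_junc_reads,
                 min_overhang = min_overhang, fdr_max = fdr_max,
                 min_abs_log2 = min_abs_log2, mirna_p = mirna_p,
                 window = window,
                 sim_config = if (is.null(sim_config))
                   simulation_config(seed = seed) else sim_config),
            class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Stages execute in dependency order (coverage -> TARs -> novel units /
#' junctions / boundaries -> expression -> integration); every output is a
#' deterministic text file under `config$outdir` and is checksummed into
#' `run_manifest.json`. Identical configuration and inputs give identical
#' manifests. A stage failure halts the run with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly: list with `parameters`, `outputs`
#'   (file -> md5), `stages_run`.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  outputs <- character(0)
  note <- function(f) outputs <<- c(outputs, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  stages_run <- character(0)

  if (config$synthetic) {
    ds <- stage("simulate", {
      d <- generate_dataset(config$sim_config)
      write_dataset(d, file.path(outdir, "inputs"))
      d
    })
    stages_run <- c(stages_run, "simulate")
    ann <- ds$annotation
    aln <- ds$alignments
    chrom_sizes <- stats::setNames(config$sim_config$genome_length,
                                   config$sim_config$chrom)
    counts_a <- ds$gene_counts$counts_a; counts_b <- ds$gene_counts$counts_b
    srna_tags <- ds$smallrna$tags
    category_refs <- ds$smallrna$category_refs
    mature_db <- ds$smallrna$mature_db
    gwas <- ds$gwas
    for (f in list.files(file.path(outdir, "inputs"), full.names = FALSE))
      note(file.path("inputs", f))
  } else {
    need <- c("annotation", "reads")
    miss <- need[!vapply(need, function(k)
      !is.null(config$inputs[[k]]) && file.exists(config$inputs[[k]]),
      logical(1))]
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    ann <- read_annotation(config$inputs$annotation)
    aln <- read_alignments(config$inputs$reads)
    chrom_sizes <- config$inputs$chrom_sizes
    if (is.null(chrom_sizes)) {
      mx <- tapply(aln$end, aln$chrom, max)
      chrom_sizes <- stats::setNames(as.integer(mx + 1000L), names(mx))
    }
    counts_a <- if (!is.null(config$inputs$counts_a))
      read_tsv_table(config$inputs$counts_a) else NULL
    counts_b <- if (!is.null(config$inputs$counts_b))
      read_tsv_table(config$inputs$counts_b) else NULL
    srna_tags <- if (!is.null(config$inputs$smallrna))
      read_tsv_table(config$inputs$smallrna) else NULL
    category_refs <- config$inputs$category_refs
    mature_db <- if (!is.null(config$inputs$mature))
      read_fasta(config$inputs$mature) else NULL
    gwas <- if (!is.null(config$inputs$gwas))
      read_tsv_table(config$inputs$gwas) else NULL
  }

  cov <- stage("coverage", compute_coverage(aln, chrom_sizes))
  de <- NULL

  if (config$stages[["tars"]]) {
    stage("tars", {
      tars <- call_tars(cov, min_depth = config$min_depth)
      units <- link_tars(tars, aln, cov)
      intergenic <- define_intergenic(ann, margin = config$margin,
                                      chrom_sizes = chrom_sizes)
      novel <- filter_novel_units(units, intergenic,
                                  min_len = config$min_len,
                                  min_avg_cov = config$min_depth)
      regions <- cluster_units(novel, gap = config$gap)
      write_tsv(tars, p("tars.tsv")); note("tars.tsv")
      write_tsv(novel$units, p("novel_units.tsv")); note("novel_units.tsv")
      write_tsv(regions, p("tar_regions.tsv")); note("tar_regions.tsv")
    })
    stages_run <- c(stages_run, "tars")
  }

  if (config$stages[["splicing"]]) {
    stage("splicing", {
      jn <- extract_junctions(aln)
      vj <- validate_junctions(jn, min_reads = config$min_junc_reads,
                               min_overhang = config$min_overhang)
      ev <- classify_events(vj, ann, cov, min_depth = config$min_depth,
                            sample = "run")
      write_tsv(vj, p("junctions.tsv")); note("junctions.tsv")
      write_tsv(ev, p("as_events.tsv")); note("as_events.tsv")
    })
    stages_run <- c(stages_run, "splicing")
  }

  if (config$stages[["boundaries"]]) {
    stage("boundaries", {
      tars <- call_tars(cov, min_depth = config$min_depth)
      models <- build_gene_models(tars, aln, ann, cov)
      extn <- detect_extensions(models)
      write_tsv(extn, p("extensions.tsv")); note("extensions.tsv")
    })
    stages_run <- c(stages_run, "boundaries")
  }

  if (config$stages[["expression"]] && !is.null(counts_a)) {
    stage("expression", {
      de <- call_de(counts_a, counts_b, fdr_max = config$fdr_max,
                    min_abs_log2 = config$min_abs_log2)
      write_tsv(de, p("de_results.tsv")); note("de_results.tsv")
      expr <- quantify(aln, ann)
      write_tsv(expr, p("expression.tsv")); note("expression.tsv")
    })
    stages_run <- c(stages_run, "expression")
  }

  if (config$stages[["smallrna"]] && !is.null(srna_tags)) {
    stage("smallrna", {
      ld <- length_distribution(srna_tags)
      write_tsv(ld$histogram, p("length_hist.tsv")); note("length_hist.tsv")
      if (!is.null(category_refs)) {
        catd <- annotate_cascade(srna_tags, category_refs)
        write_tsv(catd, p("smallrna_categories.tsv"))
        note("smallrna_categories.tsv")
        if (!is.null(mature_db)) {
          retained <- attr(catd, "retained")
          quants <- match_known(retained, mature_db,
                                clean_total = sum(srna_tags$count))
          write_tsv(quants, p("mirna_quant.tsv")); note("mirna_quant.tsv")
        }
      }
    })
    stages_run <- c(stages_run, "smallrna")
  }

  if (config$stages[["integration"]] && !is.null(gwas) && !is.null(de)) {
    stage("integration", {
      sig <- de[de$significant, , drop = FALSE]
      g <- ann$genes
      pos <- g[match(sig$gene_id, g$gene_id), c("chrom", "start", "end")]
      sig2 <- cbind(sig[, c("gene_id", "direction")], pos)
      names(sig2)[names(sig2) == "direction"] <- "direction"
      cand <- proximity_join(sig2, gwas, window = config$window)
      cand <- annotate_candidates(cand, config$inputs$ko_table)
      write_tsv(cand, p("candidates.tsv")); note("candidates.tsv")
    })
    stages_run <- c(stages_run, "integration")
  }

  params <- config[c("seed", "synthetic", "min_depth", "min_len", "margin",
                     "gap", "min_junc_reads", "min_overhang", "fdr_max",
                     "min_abs_log2", "mirna_p", "window")]
  params$stages <- as.list(config$stages)
  sums <- vapply(outputs, function(f)
    unname(tools::md5sum(file.path(outdir, f))), character(1))
  manifest <- list(parameters = params,
                   outputs = as.list(sums),
                   stages_run = stages_run)
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
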