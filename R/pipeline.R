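#' Pipeline configuration
#'
#' Collects the input paths and per-stage parameters for [run_pipeline()].
#' The configuration round-trips through JSON unchanged, and the single
#' global seed deterministically derives a per-stage seed
#' (`derive_seed(seed, stage_name)`), so any stochastic stage can be re-run
#' in isolation with identical results.
#'
#' @param corpus Path to a corpus TSV (scan dialect by default; set
#'   `corpus_dialect = "raw"` for free text).
#' @param lexicon Path to a lexicon TSV.
#' @param features Path to a gene feature TSV (header row, `gene` first
#'   column).
#' @param positives Path to a positive gene list (one symbol per line).
#' @param ontology Path to an OBO-subset ontology.
#' @param annotations Path to a 2-column `gene<TAB>term` annotation TSV.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param corpus_dialect `"scan"` or `"raw"`.
#' @param alpha Module-extraction significance threshold.
#' @param parameterization Co-mention test parameterization.
#' @param orfl_iterations,orfl_trees ORFL stage parameters.
#' @param funcsim_background,funcsim_boot Function-similarity stage sizes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, lexicon, features, positives,
                            ontology, annotations, out_dir,
                            seed = 1, corpus_dialect = c("scan", "raw"),
                            alpha = 0.01,
                            parameterization = c("literal", "universe"),
                            orfl_iterations = 1000, orfl_trees = 100,
                            funcsim_background = 100, funcsim_boot = 100) {
  structure(list(
    paths = list(corpus = corpus, lexicon = lexicon, features = features,
                 positives = positives, ontology = ontology,
                 annotations = annotations),
    out_dir = out_dir,
    seed = as.integer(seed),
    corpus_dialect = match.arg(corpus_dialect),
    alpha = alpha,
    parameterization = match.arg(parameterization),
    orfl_iterations = as.integer(orfl_iterations),
    orfl_trees = as.integer(orfl_trees),
    funcsim_background = as.integer(funcsim_background),
    funcsim_boot = as.integer(funcsim_boot)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(x$paths,
    list(out_dir = x$out_dir, seed = x$seed, corpus_dialect = x$corpus_dialect,
         alpha = x$alpha, parameterization = x$parameterization,
         orfl_iterations = x$orfl_iterations, orfl_trees = x$orfl_trees,
         funcsim_background = x$funcsim_background,
         funcsim_boot = x$funcsim_boot)))
}

#' Run the full literature-to-genes pipeline
#'
#' Sequences scan -> filter -> class tally -> concentration/retention
#' ratios -> co-mention association and modules -> positive-unlabeled gene
#' scoring -> function-consistency validation, writing each stage's output
#' (TSV/JSON) under `config$out_dir` together with a single machine-readable
#' run report (`report.json`) holding package version, global and per-stage
#' seeds, the document funnel (documents in, documents with hits, distinct
#' diseases hit), and a content hash per stage output. All referenced paths
#' are validated before any stage runs; a stage failure aborts with the
#' stage name and a classed error after writing the report with a `FAILED`
#' marker (partial outputs are retained).
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("`config` must come from pipeline_config().")
  }
  missing <- names(config$paths)[!vapply(config$paths, file.exists, logical(1))]
  if (length(missing)) {
    stop_validation(sprintf("Missing input path(s): %s",
                            paste(missing, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("autolit")),
    seed = config$seed,
    stages = list(),
    status = "RUNNING"
  )
  finish <- function(report) {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    report
  }
  stage <- function(name, fun) {
    seed <- derive_seed(config$seed, name)
    res <- tryCatch(fun(seed), error = function(e) {
      report$status <<- "FAILED"
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      finish(report)
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "autolit_pipeline_error", stage = name, parent = e)
    })
    report$stages[[name]] <<- c(list(seed = seed), res$meta)
    res$value
  }

  lexicon <- read_lexicon(config$paths$lexicon)

  scan <- stage("scan", function(seed) {
    sc <- if (config$corpus_dialect == "raw") {
      scan_documents(read_corpus(config$paths$corpus, "raw"), lexicon)
    } else {
      read_corpus(config$paths$corpus, "scan")
    }
    path <- file.path(config$out_dir, "scan.tsv")
    write_scan_result(sc, path)
    list(value = sc, meta = list(n_documents = nrow(sc), checksum = file_hash(path)))
  })

  filtered <- stage("filter", function(seed) {
    fs <- filter_hit_documents(scan)
    path <- file.path(config$out_dir, "scan_filtered.tsv")
    write_scan_result(fs, path)
    list(value = fs, meta = c(attr(fs, "funnel"), list(checksum = file_hash(path))))
  })

  counts <- stage("tally", function(seed) {
    ct <- tally_classes(filtered, lexicon)
    path <- file.path(config$out_dir, "class_counts.tsv")
    write_tsv_plain(ct, path)
    list(value = ct, meta = list(n_classes = nrow(ct), checksum = file_hash(path)))
  })

  stage("ratios", function(seed) {
    rt <- class_ratios(counts)
    path <- file.path(config$out_dir, "class_ratios.tsv")
    write_tsv_plain(rt, path)
    list(value = rt, meta = list(checksum = file_hash(path)))
  })

  assoc_modules <- stage("comodule", function(seed) {
    assoc <- pairwise_association(filtered, lexicon, config$parameterization)
    mods <- extract_modules(assoc, config$alpha)
    ppath <- file.path(config$out_dir, "pair_pvalues.tsv")
    write_tsv_plain(as_tibble(assoc), ppath)
    mpath <- file.path(config$out_dir, "modules.json")
    jsonlite::write_json(
      list(alpha = mods$alpha, method = mods$method,
           parameterization = mods$parameterization,
           modules = mods$modules, ordering = mods$ordering),
      mpath, auto_unbox = TRUE, pretty = TRUE)
    list(value = list(assoc = assoc, modules = mods),
         meta = list(n_modules = length(mods$modules),
                     checksum = file_hash(ppath)))
  })

  scores <- stage("orfl", function(seed) {
    feats <- read_feature_tsv(config$paths$features)
    pos <- readLines(config$paths$positives, encoding = "UTF-8")
    pos <- pos[nzchar(pos)]
    sc <- orfl_fit_score(feats, pos, orfl_config(
      n_iterations = config$orfl_iterations,
      trees_per_forest = config$orfl_trees, seed = seed))
    path <- file.path(config$out_dir, "orfl_scores.tsv")
    write_tsv_plain(tidy(sc), path)
    jsonlite::write_json(as.list(glance(sc)),
                         file.path(config$out_dir, "orfl_run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(value = sc, meta = list(n_scored = nrow(sc), checksum = file_hash(path)))
  })

  stage("funcsim", function(seed) {
    dag <- read_obo(config$paths$ontology)
    ann <- read_annotations(config$paths$annotations)
    ic <- compute_ic(dag, propagate_annotations(dag, ann))
    pos <- readLines(config$paths$positives, encoding = "UTF-8")
    pos <- pos[nzchar(pos)]
    grouped <- threshold_groups(scores, sort(unique(c(
      stats::quantile(scores$score, c(0.9, 0.99), na.rm = TRUE, names = FALSE), 1))))
    groups <- split(grouped$gene, grouped$group)
    groups <- groups[lengths(groups) > 0]
    gc <- group_consistency(groups, pos, dag, ic, ann,
                            n_background = config$funcsim_background,
                            n_boot = config$funcsim_boot, seed = seed)
    path <- file.path(config$out_dir, "group_consistency.tsv")
    write_tsv_plain(as_tibble(gc), path)
    list(value = gc, meta = list(n_groups = nrow(gc), checksum = file_hash(path)))
  })

  report$status <- "OK"
  invisible(finish(report))
}

file_hash <- function(path) unname(tools::md5sum(path))

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene feature TSV
#'
#' Header row of feature names, first column `gene`.
#'
#' @param path File path.
#' @return Tibble with a `gene` column and numeric feature columns.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") names(df)[1] <- "gene"
  as_tibble(df)
}

#' Read a 2-column gene-term annotation TSV
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "term"),
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Write a miniature demo dataset
#'
#' Creates a complete, byte-deterministic input set for [run_pipeline()]:
#' a synthetic disease lexicon over the 22 packaged disease classes, a
#' synthetic scanned corpus with one planted co-mention module, a gene
#' feature matrix whose positive set is the packaged 61-gene list, a toy
#' ontology with annotations, and a ready-to-run `config.json`. The planted
#' structure lets the full pipeline run end to end in well under two
#' minutes.
#'
#' @param output_dir Directory to create files in.
#' @param seed Integer seed; identical seeds give identical bytes.
#' @return The path of the written config, invisibly.
#' @export
make_demo <- function(output_dir, seed = 1) {
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir) || file.access(output_dir, 2) != 0) {
    abort(sprintf("Cannot write to `%s`.", output_dir), class = "autolit_io_error")
  }
  classes <- load_fixture("table1_counts")$class

  set.seed(derive_seed(seed, "demo_lexicon"))
  raw <- tibble(
    class = rep(classes, each = 8),
    name = paste(rep(tolower(classes), each = 8), "disorder",
                 rep(1:8, times = length(classes)))
  )
  lexicon <- merge_lexicon(raw[, c("name", "class")])
  lex_path <- file.path(output_dir, "lexicon.tsv")
  write_lexicon(lexicon, lex_path)

  boosts <- tibble(class_a = c("Nutritional", "Nutritional", "Immunological"),
                   class_b = c("Immunological", "Skeletal", "Skeletal"),
                   boost = 8)
  spec <- corpus_spec(
    n_documents = 2000,
    class_weights = setNames(rep(1, length(classes)), classes),
    comention_boost = boosts,
    mentions_per_doc = 2.5,
    seed = derive_seed(seed, "demo_corpus"))
  corpus_path <- file.path(output_dir, "corpus.tsv")
  write_scan_result(generate_corpus(spec, lexicon), corpus_path)

  adgs <- load_fixture("table2_adgs")
  fsim <- generate_features(feature_spec(
    n_genes = 400, n_features = 30, n_informative = 8, effect_size = 2,
    n_positives = length(adgs), seed = derive_seed(seed, "demo_features")))
  feats <- fsim$features
  feats$gene[match(fsim$positives, feats$gene)] <- adgs
  feat_path <- file.path(output_dir, "features.tsv")
  write_tsv_plain(feats, feat_path)
  pos_path <- file.path(output_dir, "positives.txt")
  writeLines(adgs, pos_path, useBytes = TRUE)

  toy <- generate_toy_ontology(depth = 4, branching = 2, n_genes = 1,
                               seed = derive_seed(seed, "demo_ontology"))
  set.seed(derive_seed(seed, "demo_annotations"))
  leaves <- setdiff(toy$dag$terms, unique(unlist(toy$dag$parents)))
  ann <- tibble(gene = rep(feats$gene, each = 2),
                term = sample(leaves, 2 * nrow(feats), replace = TRUE)) |>
    distinct()
  obo_path <- file.path(output_dir, "ontology.obo")
  write_obo(toy$dag, obo_path)
  ann_path <- file.path(output_dir, "annotations.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  cfg <- pipeline_config(
    corpus = corpus_path, lexicon = lex_path, features = feat_path,
    positives = pos_path, ontology = obo_path, annotations = ann_path,
    out_dir = file.path(output_dir, "out"), seed = seed,
    orfl_iterations = 200, orfl_trees = 50,
    funcsim_background = 50, funcsim_boot = 50)
  cfg_path <- file.path(output_dir, "config.json")
  write_pipeline_config(cfg, cfg_path)
  invisible(cfg_path)
}
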