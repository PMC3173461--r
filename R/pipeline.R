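#' Default pipeline configuration
#'
#' The bundled configuration drives a fully synthetic end-to-end run that
#' emulates the study design: a dye-swap time course (7 days x 2 treatments
#' x 3 replicates, 84 labelled sample-channels) plus a 15 + 15 field test
#' set, preprocessed, tested for differential expression, and swept over
#' nine diagnostic-set sizes and four kernels.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; every stage derives its stream from it.
#' @return A nested configuration list.
#' @export
default_config <- function(out_dir = "pistatus_out", seed = 1L) {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "pistatus")) |>
    utils::modifyList(list(out_dir = out_dir, seed = as.integer(seed)))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort_pistatus(sprintf("Config file does not exist: %s", config),
                     "pistatus_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_pistatus("`config` must be a list or a YAML file path.",
                   "pistatus_config_error")
  }
  base <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                      package = "pistatus"))
  cfg <- utils::modifyList(base, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort_pistatus("`seed` must be a single integer.",
                   "pistatus_config_error")
  }
  cfg
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

provenance_for <- function(cfg) {
  c(
    package = paste0("pistatus ",
                     as.character(utils::packageVersion("pistatus"))),
    seed = as.character(cfg$seed),
    params_hash = rlang::hash(cfg)
  )
}

write_stage <- function(cfg, x, name) {
  write_pistatus_tsv(x, stage_path(cfg, name), provenance = provenance_for(cfg))
}

cfg_preprocess_params <- function(cfg) {
  p <- cfg$preprocess
  preprocess_params(
    lowess_span = p$lowess_span, control_floor = p$control_floor,
    raw_floor = p$raw_floor, raw_floor_timepoints = p$raw_floor_timepoints,
    flat_band = unlist(p$flat_band), absent_frac = p$absent_frac
  )
}

cfg_de_params <- function(cfg) {
  d <- cfg$de
  de_params(alpha = d$alpha, fc_threshold = d$fc_threshold,
            min_timepoints = d$min_timepoints, n_groups = d$n_groups)
}

read_meta <- function(cfg, name) {
  m <- read_pistatus_tsv(stage_path(cfg, name))
  m$sample_id <- as.character(m$sample_id)
  m
}

## Normalized one-colour channel features straight from the simulated raw
## data, so classifier stages can run directly after `simulate`.
pipeline_channels <- function(cfg) {
  raw <- read_pistatus_tsv(stage_path(cfg, "raw.tsv"))
  meta <- read_meta(cfg, "meta.tsv")
  normalized_channels(raw, meta, cfg_preprocess_params(cfg))
}

stage_simulate <- function(cfg) {
  s <- cfg$simulate
  design <- sim_design(
    n_genes = s$n_genes, frac_responsive = s$frac_responsive,
    effect_fold = s$effect_fold, noise_sd = s$noise_sd,
    dye_bias = unlist(s$dye_bias), frac_absent = s$frac_absent,
    frac_low_signal = s$frac_low_signal, seed = cfg$seed
  )
  sim <- simulate_timecourse(design)
  field <- generate_field_set(sim$truth, n_per_class = s$field$n_per_class,
                              attenuation = s$field$attenuation,
                              noise_sd = s$field$noise_sd,
                              seed = derive_seed(cfg$seed, 11L))
  write_stage(cfg, sim$raw, "raw.tsv")
  write_stage(cfg, sim$meta, "meta.tsv")
  write_stage(cfg, sim$flags, "flags.tsv")
  write_stage(cfg, sim$truth, "truth.tsv")
  write_stage(cfg, field$expr, "field_expr.tsv")
  write_stage(cfg, field$meta, "field_meta.tsv")
  invisible(c("raw.tsv", "meta.tsv", "flags.tsv", "truth.tsv",
              "field_expr.tsv", "field_meta.tsv"))
}

stage_preprocess <- function(cfg) {
  raw <- read_pistatus_tsv(stage_path(cfg, "raw.tsv"))
  meta <- read_meta(cfg, "meta.tsv")
  flags_path <- stage_path(cfg, "flags.tsv")
  flags <- if (file.exists(flags_path)) read_pistatus_tsv(flags_path) else NULL
  params <- cfg_preprocess_params(cfg)
  channels <- normalized_channels(raw, meta, params)
  scaled <- suppressWarnings(median_scale(channels))
  kept <- match(scaled$gene_id, raw$gene_id)
  filt <- prefilter(scaled, raw[kept, ],
                    if (is.null(flags)) NULL else flags[kept, ],
                    meta, params)
  write_stage(cfg, channels, "channels.tsv")
  write_stage(cfg, scaled, "normalized.tsv")
  write_stage(cfg, filt$matrix, "filtered.tsv")
  write_stage(cfg, filt$report, "removal_report.tsv")
  invisible(c("channels.tsv", "normalized.tsv", "filtered.tsv",
              "removal_report.tsv"))
}

stage_de <- function(cfg) {
  x <- read_pistatus_tsv(stage_path(cfg, "filtered.tsv"))
  meta <- read_meta(cfg, "meta.tsv")
  fc <- fold_changes(x, meta)
  p <- anova_pvalues(x, meta)
  de <- call_de(fc, p, cfg_de_params(cfg))
  write_stage(cfg, de, "de_table.tsv")
  invisible("de_table.tsv")
}

stage_cluster <- function(cfg) {
  de <- read_pistatus_tsv(stage_path(cfg, "de_table.tsv"))
  params <- cfg_de_params(cfg)
  n_de <- sum(de$de)
  n_groups <- min(params$n_groups, n_de)
  if (n_groups < 1) {
    abort_pistatus("No DE genes to cluster.", "pistatus_data_error")
  }
  de <- hierarchical_cluster(de, n_groups)
  sig <- group_signatures(de, params$fc_threshold)
  write_stage(cfg, de, "de_table.tsv")
  write_stage(cfg, sig, "group_signatures.tsv")
  invisible(c("de_table.tsv", "group_signatures.tsv"))
}

stage_enrich <- function(cfg) {
  if (is.null(cfg$enrich$annotation)) {
    abort_pistatus("`enrich.annotation` (gene_id/term TSV) is not configured.",
                   "pistatus_config_error")
  }
  ann <- read_pistatus_tsv(cfg$enrich$annotation)
  de <- read_pistatus_tsv(stage_path(cfg, "de_table.tsv"))
  res <- term_enrichment(de$gene_id[de$de], ann, de$gene_id)
  write_stage(cfg, res, "enrichment.tsv")
  invisible("enrichment.tsv")
}

pipeline_training <- function(cfg) {
  channels_path <- stage_path(cfg, "channels.tsv")
  channels <- if (file.exists(channels_path)) {
    read_pistatus_tsv(channels_path)
  } else {
    pipeline_channels(cfg)
  }
  meta <- read_meta(cfg, "meta.tsv")
  labels <- build_training_labels(meta,
                                  replete_days = unlist(cfg$classify$replete_days))
  list(features = prepare_features(channels), labels = labels)
}

stage_select <- function(cfg) {
  tr <- pipeline_training(cfg)
  scores <- golub_scores(log2_features(tr$features), tr$labels$class)
  sel <- select_diagnostic(scores, cfg$classify$k)
  write_stage(cfg, scores, "golub_scores.tsv")
  write_stage(cfg, sel, "diagnostic_genes.tsv")
  invisible(c("golub_scores.tsv", "diagnostic_genes.tsv"))
}

stage_train <- function(cfg) {
  tr <- pipeline_training(cfg)
  sel <- read_pistatus_tsv(stage_path(cfg, "diagnostic_genes.tsv"))
  x <- tr$features[match(sel$gene_id, tr$features$gene_id), ]
  fit <- svm_train(x, tr$labels$class, parse_kernel(cfg$classify$kernel),
                   C = cfg$classify$C, normalize = "l2")
  path <- stage_path(cfg, "model.json")
  write_svm_model(fit, path)
  invisible("model.json")
}

stage_predict <- function(cfg) {
  fit <- read_svm_model(stage_path(cfg, "model.json"))
  field <- read_pistatus_tsv(stage_path(cfg, "field_expr.tsv"))
  pred <- predict_margins(fit, prepare_features(field))
  write_stage(cfg, pred, "field_predictions.tsv")
  invisible("field_predictions.tsv")
}

stage_grid <- function(cfg) {
  tr <- pipeline_training(cfg)
  field <- read_pistatus_tsv(stage_path(cfg, "field_expr.tsv"))
  field_meta <- read_meta(cfg, "field_meta.tsv")
  grid <- evaluate_grid(
    tr$features, tr$labels$class,
    prepare_features(field), field_meta$class,
    sizes = unlist(cfg$classify$sizes),
    kernels = unlist(cfg$classify$kernels),
    C = cfg$classify$C
  )
  write_stage(cfg, grid, "grid.tsv")
  invisible("grid.tsv")
}

stage_transfer <- function(cfg) {
  tcfg <- cfg$transfer
  needed <- c("map", "reference_expr", "reference_meta", "test_expr")
  if (any(vapply(tcfg[needed], is.null, logical(1)))) {
    abort_pistatus(
      "transfer needs `map`, `reference_expr`, `reference_meta` and `test_expr` paths.",
      "pistatus_config_error"
    )
  }
  map <- read_pistatus_tsv(tcfg$map)
  sel <- read_pistatus_tsv(stage_path(cfg, "diagnostic_genes.tsv"))
  mapping <- map_features(sel$gene_id, map)
  reference <- read_pistatus_tsv(tcfg$reference_expr)
  ref_meta <- read_pistatus_tsv(tcfg$reference_meta)
  test <- read_pistatus_tsv(tcfg$test_expr)
  res <- cross_platform_classify(mapping, reference, ref_meta$class, test,
                                 spec = cfg$classify$kernel,
                                 C = cfg$classify$C)
  write_stage(cfg, res$margins, "transfer_predictions.tsv")
  write_stage(cfg, mapping$records, "mapping_records.tsv")
  invisible(c("transfer_predictions.tsv", "mapping_records.tsv"))
}

#' Run the marker-discovery pipeline
#'
#' Single entry point wiring the synthetic-data, preprocessing,
#' differential-expression, classification and transfer stages through a
#' structured configuration. Every stage reads its inputs from, and writes
#' its outputs to, `out_dir` as UTF-8 TSV files with a provenance header
#' (package version, seed, parameter hash); all randomness derives from the
#' config seed, so identical config + seed give byte-identical artifacts.
#'
#' @param config Configuration list or YAML file path; missing entries fall
#'   back to [default_config()].
#' @param subcommand One of `"simulate"`, `"preprocess"`, `"de"`,
#'   `"cluster"`, `"enrich"`, `"select"`, `"train"`, `"predict"`, `"grid"`,
#'   `"transfer"`, or `"all"` (simulate through grid).
#' @param overrides Named list merged over the config (e.g.
#'   `list(seed = 7)`).
#' @return Invisibly, the file names written by the stage(s).
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' run_pipeline(list(out_dir = dir, simulate = list(n_genes = 200)),
#'              "simulate")
#' }
run_pipeline <- function(config = default_config(),
                         subcommand = c("all", "simulate", "preprocess",
                                        "de", "cluster", "enrich", "select",
                                        "train", "predict", "grid",
                                        "transfer"),
                         overrides = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- read_config(config)
  if (length(overrides) > 0) cfg <- utils::modifyList(cfg, overrides)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(
    simulate = stage_simulate, preprocess = stage_preprocess,
    de = stage_de, cluster = stage_cluster, enrich = stage_enrich,
    select = stage_select, train = stage_train, predict = stage_predict,
    grid = stage_grid, transfer = stage_transfer
  )
  run <- if (subcommand == "all") {
    c("simulate", "preprocess", "de", "cluster", "select", "train",
      "predict", "grid")
  } else {
    subcommand
  }
  written <- character()
  for (s in run) {
    written <- c(written, stages[[s]](cfg))
  }
  invisible(written)
}
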