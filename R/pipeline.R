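# Orchestration: the EAG analysis (annotations -> coverage -> clustering ->
# pause metrics -> stratification) and the two-condition perturbation
# comparison, driven by a validated config and writing a deterministic
# artifact bundle plus a run manifest.

.cfg_defaults <- list(
  annotation_format = "bed12", flank_bp = 4000, bin_width = 50,
  extension_bp = 200, k = 2, seed = 1L, min_distance_bp = 4000,
  collapse_rule = "longest", low_intensity_quantile = 0,
  n_top_expressed = 100, restarts = 50L, name_patterns = NULL,
  core_list = character(), variant_list = character(),
  nascent_reads = NULL, expression = NULL, truth = NULL, out_dir = NULL
)

#' Build and validate an analysis configuration
#'
#' Fields may reference files (paths) or hold in-memory objects (alignment
#' data frames, a `GeneSet`, a named `chrom_sizes` vector). Every malformed
#' field is rejected with a field-specific message.
#'
#' @param signal_reads,mock_reads BED6 path or alignment data frame.
#' @param genes Annotation path or `GeneSet`.
#' @param chrom_sizes Two-column file path or named integer vector.
#' @param ... Optional fields and overrides: `nascent_reads`, `expression`
#'   (TSV path or data frame), `truth` (truth table for planted-label
#'   evaluation), `annotation_format`, `flank_bp`, `bin_width`,
#'   `extension_bp`, `k`, `seed`, `restarts`, `min_distance_bp`,
#'   `collapse_rule`, `low_intensity_quantile`, `n_top_expressed`,
#'   `name_patterns`, `core_list`, `variant_list`, `out_dir`.
#' @return Validated `AnalysisConfig` (a list).
#' @export
analysis_config <- function(signal_reads, mock_reads, genes, chrom_sizes,
                            ...) {
  cfg <- utils::modifyList(
    .cfg_defaults,
    c(list(signal_reads = signal_reads, mock_reads = mock_reads,
           genes = genes, chrom_sizes = chrom_sizes), list(...)))
  unknown <- setdiff(names(cfg), c(names(.cfg_defaults), "signal_reads",
                                   "mock_reads", "genes", "chrom_sizes"))
  .assert(length(unknown) == 0L, "unknown config field(s): ",
          paste(unknown, collapse = ", "))
  # YAML round-trips empty vectors as lists; normalise the list-ish fields
  cfg$core_list <- as.character(unlist(cfg$core_list))
  cfg$variant_list <- as.character(unlist(cfg$variant_list))
  if (!is.null(cfg$name_patterns))
    cfg$name_patterns <- unlist(cfg$name_patterns)
  for (f in c("signal_reads", "mock_reads", "nascent_reads", "genes",
              "expression", "chrom_sizes", "truth")) {
    v <- cfg[[f]]
    if (is.character(v))
      .assert(file.exists(v), "config field '", f, "': file not found: ", v)
  }
  .assert(cfg$annotation_format %in% c("bed12", "refflat", "gtf"),
          "config field 'annotation_format' must be bed12/refflat/gtf")
  for (f in c("flank_bp", "bin_width", "extension_bp", "k",
              "min_distance_bp", "restarts")) {
    v <- cfg[[f]]
    .assert(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 1,
            "config field '", f, "' must be a positive number")
  }
  .assert(cfg$flank_bp %% cfg$bin_width == 0,
          "config field 'flank_bp' must be a multiple of bin_width")
  .assert(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
          "config field 'seed' must be a single integer")
  .assert(cfg$low_intensity_quantile >= 0 && cfg$low_intensity_quantile < 1,
          "config field 'low_intensity_quantile' must be in [0, 1)")
  .assert(cfg$collapse_rule %in% c("longest", "union"),
          "config field 'collapse_rule' must be longest or union")
  structure(cfg, class = "AnalysisConfig")
}

#' Write / read a path-based configuration as YAML
#' @param cfg An `AnalysisConfig` whose data fields are all paths.
#' @param path YAML file path.
#' @return `write_analysis_config()` returns `path` invisibly;
#'   `read_analysis_config()` a validated `AnalysisConfig`.
#' @export
write_analysis_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  .assert(all(vapply(flat, function(v)
    is.character(v) | is.numeric(v), logical(1))),
    "only path/scalar configs round-trip to YAML")
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  flat <- yaml::read_yaml(path)
  do.call(analysis_config, flat)
}

.load_chrom_sizes <- function(x) {
  if (is.character(x)) {
    df <- read.delim(x, header = FALSE)
    setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
  } else {
    .assert(is.numeric(x) && !is.null(names(x)),
            "chrom_sizes must be a named numeric vector or a file path")
    x
  }
}

.load_reads <- function(x) {
  if (is.character(x)) read_alignments_bed(x) else x
}

.stage <- function(manifest, name, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  manifest$stages <- c(manifest$stages, name)
  list(manifest = manifest, value = res)
}

.input_checksums <- function(cfg) {
  paths <- Filter(is.character,
                  unclass(cfg)[c("signal_reads", "mock_reads",
                                 "nascent_reads", "genes", "expression",
                                 "chrom_sizes", "truth")])
  if (length(paths) == 0L) return(NULL)
  sums <- tools::md5sum(unlist(paths))
  as.list(setNames(unname(sums), names(paths)))
}

#' Run the EAG occupancy analysis end to end
#'
#' Executes annotations -> coverage -> anchored matrices -> K-means
#' clustering -> pause metrics -> expression stratification, and writes the
#' artifact bundle (kept genes, matrices, cluster tables, metrics, profiles)
#' plus a `manifest.yaml` with per-stage gene counts, the seed and input
#' checksums. Re-running with the same config and seed reproduces every
#' output byte for byte.
#'
#' @param cfg An `AnalysisConfig`.
#' @return List: `genes` (filtered `GeneSet`), `tracks`, `matrices`
#'   (`signal`, `mock` EAG matrices), `clusters` (`ClusterResult`),
#'   `profiles`, `metrics`, `indices`, `stratify` (or `NULL`), `manifest`.
#' @export
run_eag_analysis <- function(cfg) {
  .assert(inherits(cfg, "AnalysisConfig"), "cfg must be an AnalysisConfig")
  manifest <- list(seed = as.integer(cfg$seed), stages = character(),
                   counts = list(), checksums = .input_checksums(cfg))

  st <- .stage(manifest, "annotations", {
    gs <- if (is.character(cfg$genes))
      read_gene_models(cfg$genes, cfg$annotation_format) else cfg$genes
    n0 <- nrow(gs$genes)
    gs <- collapse_transcripts(gs, cfg$collapse_rule)
    gs <- assign_gene_class(gs, cfg$core_list, cfg$variant_list,
                            cfg$name_patterns)
    gs <- filter_isolated(gs, cfg$min_distance_bp)
    list(gs = gs, n_input = n0)
  })
  manifest <- st$manifest
  gs <- st$value$gs
  manifest$counts$transcripts_in <- st$value$n_input
  manifest$counts$genes_isolated <- nrow(gs$genes)

  chrom_sizes <- .load_chrom_sizes(cfg$chrom_sizes)
  st <- .stage(manifest, "coverage", {
    make_track <- function(x) {
      reads <- .load_reads(x)
      frags <- extend_reads(reads, cfg$extension_bp, chrom_sizes)
      build_coverage(frags, cfg$bin_width, chrom_sizes,
                     normalization = "rpm")
    }
    list(signal = make_track(cfg$signal_reads),
         mock = make_track(cfg$mock_reads))
  })
  manifest <- st$manifest
  tracks <- st$value
  manifest$counts$signal_fragments <- tracks$signal$total_fragments
  manifest$counts$mock_fragments <- tracks$mock$total_fragments

  st <- .stage(manifest, "matrices", {
    list(signal = anchor_matrix(tracks$signal, gs, "EAG", cfg$flank_bp),
         mock = anchor_matrix(tracks$mock, gs, "EAG", cfg$flank_bp))
  })
  manifest <- st$manifest
  matrices <- st$value

  st <- .stage(manifest, "clustering", {
    cr <- kmeans_cluster(matrices$signal, k = cfg$k, seed = cfg$seed,
                         restarts = cfg$restarts)
    list(cr = cr, profiles = cluster_profiles(matrices$signal, cr))
  })
  manifest <- st$manifest
  clusters <- st$value$cr
  profiles <- st$value$profiles
  manifest$counts$cluster_sizes <- as.list(setNames(
    as.integer(profiles$sizes), paste0("cluster", seq_len(clusters$k))))

  st <- .stage(manifest, "pause_metrics", {
    floor_bg <- estimate_track_background(tracks$signal, gs)
    metrics <- pause_metrics(matrices$signal, matrices$mock,
                             decay_background = floor_bg,
                             fit_from_bp = cfg$extension_bp)
    indices <- pausing_indices(tracks$signal, gs)
    list(metrics = metrics, indices = indices, floor = floor_bg)
  })
  manifest <- st$manifest
  metrics <- st$value$metrics
  indices <- st$value$indices
  manifest$counts$shape_classes <- as.list(table(metrics$shape_class))

  stratify <- NULL
  if (!is.null(cfg$expression)) {
    st <- .stage(manifest, "stratify", {
      et <- if (is.character(cfg$expression)) {
        read_expression(cfg$expression,
                        low_intensity_quantile = cfg$low_intensity_quantile)
      } else {
        structure(list(values = setNames(rowMeans(cfg$expression[, -1L]),
                                         cfg$expression[[1L]]),
                       replicates = ncol(cfg$expression) - 1L,
                       filter_log = "in-memory table"),
                  class = "ExpressionTable")
      }
      n_top <- min(cfg$n_top_expressed,
                   sum(names(et$values) %in% gs$genes$name))
      list(table = et,
           top = select_top_expressed(et, n_top, gs),
           by_cluster = cluster_expression_summary(clusters, et))
    })
    manifest <- st$manifest
    stratify <- st$value
  }

  if (!is.null(cfg$truth)) {
    tr <- if (is.character(cfg$truth)) read.delim(cfg$truth) else cfg$truth
    lab <- tr$pause_class[match(names(clusters$assignments), tr$gene)]
    if (!anyNA(lab))
      manifest$planted_ari <- adjusted_rand_index(clusters$assignments, lab)
  }

  if (!is.null(cfg$out_dir)) {
    out <- cfg$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_gene_bed(gs, file.path(out, "genes_kept.bed"),
                   file.path(out, "filter_log.tsv"))
    write_anchor_matrix(matrices$signal, file.path(out, "eag_signal.tsv"),
                        tracks$signal)
    write_anchor_matrix(matrices$mock, file.path(out, "eag_mock.tsv"),
                        tracks$mock)
    write_cluster_result(clusters, out)
    ord <- heatmap_order(matrices$signal, clusters)
    .write_tsv(data.frame(gene = rownames(matrices$signal)[ord],
                          cluster = unname(clusters$assignments[ord])),
               file.path(out, "heatmap_row_order.tsv"))
    prof <- data.frame(offset_bp = anchor_offsets(matrices$signal),
                       signal = mean_profile(matrices$signal),
                       mock = mean_profile(matrices$mock),
                       t(profiles$profiles))
    names(prof) <- c("offset_bp", "signal_mean", "mock_mean",
                     paste0("cluster", seq_len(clusters$k)))
    .write_tsv(prof, file.path(out, "mean_profiles.tsv"))
    .write_tsv(metrics, file.path(out, "pause_metrics.tsv"))
    .write_tsv(indices, file.path(out, "pausing_indices.tsv"))
    if (!is.null(stratify))
      .write_tsv(stratify$by_cluster,
                 file.path(out, "cluster_expression.tsv"))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  }

  list(genes = gs, tracks = tracks, matrices = matrices,
       clusters = clusters, profiles = profiles, metrics = metrics,
       indices = indices, stratify = stratify, manifest = manifest)
}

#' Run the two-condition perturbation comparison
#'
#' Builds rpm tracks for each condition, evaluates the qPCR-style region
#' panel mock-normalised per condition, and summarises treated/untreated
#' ratios per gene class and region with bootstrap confidence intervals.
#'
#' @param untreated,treated Lists with `signal_reads` and `mock_reads`
#'   (paths or alignment data frames).
#' @param genes `GeneSet` or annotation path (classes must be assignable;
#'   see `name_patterns`).
#' @param chrom_sizes Named vector or path.
#' @param panel Region panel (default [default_region_panel()]).
#' @param extension_bp,bin_width,seed,n_boot See [analysis_config()] /
#'   [condition_ratio()].
#' @param annotation_format,name_patterns,core_list,variant_list Annotation
#'   handling for path input.
#' @param out_dir Optional output directory for the tidy ratio TSV and the
#'   CI summary TSV.
#' @return List: `values` (per condition region signals), `ratios`,
#'   `summary`.
#' @export
run_perturbation_analysis <- function(untreated, treated, genes, chrom_sizes,
                                      panel = default_region_panel(),
                                      extension_bp = 200, bin_width = 50,
                                      seed = 1L, n_boot = 1000,
                                      annotation_format = "bed12",
                                      name_patterns = NULL,
                                      core_list = character(),
                                      variant_list = character(),
                                      out_dir = NULL) {
  for (cond in list(untreated, treated))
    .assert(!is.null(cond$signal_reads) && !is.null(cond$mock_reads),
            "each condition needs signal_reads and mock_reads")
  chrom_sizes <- .load_chrom_sizes(chrom_sizes)
  gs <- if (is.character(genes)) {
    g <- read_gene_models(genes, annotation_format)
    g <- collapse_transcripts(g)
    assign_gene_class(g, core_list, variant_list, name_patterns)
  } else genes
  make_track <- function(x) {
    frags <- extend_reads(.load_reads(x), extension_bp, chrom_sizes)
    build_coverage(frags, bin_width, chrom_sizes, normalization = "rpm")
  }
  values <- lapply(list(untreated = untreated, treated = treated),
                   function(cond) {
    region_signal(make_track(cond$signal_reads),
                  make_track(cond$mock_reads), gs, panel)
  })
  cr <- condition_ratio(values$treated, values$untreated, n_boot = n_boot,
                        seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tidy <- rbind(
      data.frame(condition = "untreated", values$untreated),
      data.frame(condition = "treated", values$treated))
    .write_tsv(tidy, file.path(out_dir, "region_signals.tsv"))
    .write_tsv(cr$ratios, file.path(out_dir, "region_ratios.tsv"))
    .write_tsv(cr$summary, file.path(out_dir, "ratio_summary.tsv"))
  }
  list(values = values, ratios = cr$ratios, summary = cr$summary)
}
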