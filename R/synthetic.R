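# Parametric Pol II occupancy simulator with planted pause shapes.
#
# The per-base occupancy model has four components: a promoter-proximal
# Gaussian peak centred a few tens of bp downstream of the TSS, a uniform
# gene-body plateau, an exponentially decaying downstream-of-EAG pause
# (narrow, core-histone-like: lambda 250 bp capped at 1 kb; broad,
# poly(A)+-like: lambda 1500 bp capped at 8 kb), and a uniform genomic
# background. Reads are 32-bp tags whose 5' ends are sampled proportionally
# to intensity, to be extended by the pipeline exactly like real tags.

.PAUSE_DEFAULTS <- list(
  H = list(pause_decay_bp = 250, pause_cap_bp = 1000),
  PA = list(pause_decay_bp = 1500, pause_cap_bp = 8000)
)

#' Occupancy model parameters for one gene
#'
#' @param pause_class `"H"` (narrow, core-histone-like) or `"PA"` (broad,
#'   poly(A)+-like); sets the decay length and cap.
#' @param tss_amplitude Peak height of the promoter-proximal Gaussian
#'   (occupancy units; the Gaussian has unit peak, not unit mass).
#' @param tss_offset_bp Peak centre downstream of the TSS (default 30 bp,
#'   the promoter-proximal stall position).
#' @param tss_sd_bp Gaussian width (default 150 bp).
#' @param body_level Gene-body plateau level.
#' @param pause_amplitude Height of the downstream pause at the EAG.
#' @param pause_decay_bp,pause_cap_bp Decay length and hard cap of the
#'   downstream pause; defaults by class.
#' @param background_rate Uniform per-bp background intensity.
#' @return Named list of parameters.
#' @export
occupancy_params <- function(pause_class = c("PA", "H"), tss_amplitude = 8,
                             tss_offset_bp = 30, tss_sd_bp = 150,
                             body_level = 0.5, pause_amplitude = 5,
                             pause_decay_bp = NULL, pause_cap_bp = NULL,
                             background_rate = 0.02) {
  pause_class <- match.arg(pause_class)
  d <- .PAUSE_DEFAULTS[[pause_class]]
  p <- list(
    pause_class = pause_class,
    tss_amplitude = tss_amplitude, tss_offset_bp = tss_offset_bp,
    tss_sd_bp = tss_sd_bp, body_level = body_level,
    pause_amplitude = pause_amplitude,
    pause_decay_bp = pause_decay_bp %||% d$pause_decay_bp,
    pause_cap_bp = pause_cap_bp %||% d$pause_cap_bp,
    background_rate = background_rate
  )
  .assert(all(unlist(p[c("tss_amplitude", "body_level", "pause_amplitude",
                         "background_rate")]) >= 0) &&
            p$pause_decay_bp > 0,
          "amplitudes must be >= 0 and pause_decay_bp > 0")
  p
}

#' Generate a synthetic genome with planted gene classes
#'
#' Genes are laid out sequentially with random spacing and strand,
#' class-specific lengths (core-histone genes are short and intronless;
#' poly(A)+ genes longer with 2-5 exons) and classes drawn from `class_mix`.
#' The default spacing keeps every gene in the isolated regime (>= 4 kb from
#' its neighbours); a clustered-histone layout is obtained by shrinking
#' `spacing_range` to e.g. `c(800, 1000)`.
#'
#' @param n_genes Number of genes.
#' @param class_mix Named proportions over `c(H, PA)`; must sum to 1.
#' @param gene_length_range Named list of `c(min, max)` lengths per class.
#' @param spacing_range `c(min, max)` intergenic spacing in bp.
#' @param n_chrom Number of chromosomes (genes dealt round-robin).
#' @param seed RNG seed; the same seed reproduces the genome exactly.
#' @return List: `chrom_sizes` (named, multiples of 50), `genes` (a
#'   `GeneSet` with `gene_class` set to `core_histone`/`other`), `truth`
#'   (data frame: gene, pause_class, all occupancy parameters, multiplier,
#'   expected noiseless extent) and `seed`.
#' @export
make_genome <- function(n_genes = 200,
                        class_mix = c(H = 0.5, PA = 0.5),
                        gene_length_range = list(H = c(400, 800),
                                                 PA = c(5000, 8000)),
                        spacing_range = c(20000, 30000),
                        n_chrom = 2, seed = 1L,
                        multiplier_sdlog = 0, ...) {
  .assert(abs(sum(class_mix) - 1) < 1e-8, "class proportions must sum to 1")
  .assert(all(spacing_range > 0) && n_genes >= 1, "invalid layout ranges")
  params_extra <- list(...)
  .with_seed(seed, {
    classes <- sample(names(class_mix), n_genes, replace = TRUE,
                      prob = class_mix)
    mult <- exp(rnorm(n_genes, 0, multiplier_sdlog))
    chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
    rows <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    cursor <- setNames(rep(10000, n_chrom), paste0("chr", seq_len(n_chrom)))
    for (i in seq_len(n_genes)) {
      cls <- classes[i]
      lr <- gene_length_range[[cls]]
      len <- round(runif(1, lr[1], lr[2]))
      ch <- chrom_of[i]
      start <- cursor[[ch]]
      end <- start + len
      strand <- sample(c("+", "-"), 1)
      if (cls == "H") {
        es <- start; ee <- end
      } else {
        n_ex <- sample(2:5, 1)
        cuts <- sort(sample(seq(start + 100, end - 100, by = 50),
                            2 * (n_ex - 1)))
        es <- c(start, cuts[seq(2, length(cuts), by = 2)])
        ee <- c(cuts[seq(1, length(cuts), by = 2)], end)
      }
      name <- sprintf("%s_%03d", ifelse(cls == "H", "HISTg", "PAg"), i)
      rows[[i]] <- data.frame(
        chrom = ch, start = start, end = end, strand = strand,
        name = name, transcript_id = paste0(name, ".1"),
        exon_starts = I(list(es)), exon_ends = I(list(ee)),
        gene_class = ifelse(cls == "H", "core_histone", "other"),
        stringsAsFactors = FALSE
      )
      p <- do.call(occupancy_params, c(list(pause_class = cls), params_extra))
      truth[[i]] <- data.frame(
        gene = name, pause_class = cls, chrom = ch, strand = strand,
        tss_amplitude = p$tss_amplitude * mult[i],
        tss_offset_bp = p$tss_offset_bp, tss_sd_bp = p$tss_sd_bp,
        body_level = p$body_level * mult[i],
        pause_amplitude = p$pause_amplitude * mult[i],
        pause_decay_bp = p$pause_decay_bp, pause_cap_bp = p$pause_cap_bp,
        background_rate = p$background_rate,
        multiplier = mult[i]
      )
      cursor[[ch]] <- end + round(runif(1, spacing_range[1], spacing_range[2]))
    }
    truth <- do.call(rbind, truth)
    truth$expected_extent_bp <- pmin(
      truth$pause_cap_bp,
      truth$pause_decay_bp *
        log(pmax(truth$pause_amplitude / truth$background_rate, 1))
    )
    chrom_sizes <- setNames(
      as.integer(ceiling((cursor + 10000) / 50) * 50), names(cursor))
    genes <- .new_gene_set(.finish_genes(do.call(rbind, rows)),
                           provenance = sprintf("synthetic genome seed=%d",
                                                seed))
    list(chrom_sizes = chrom_sizes, genes = genes, truth = truth,
         seed = as.integer(seed))
  })
}

#' Per-base occupancy intensity for one gene
#'
#' `intensity(x) = background + tss_amplitude * exp(-(t - offset)^2 / 2sd^2)
#' + body_level * [x in body] + pause_amplitude * exp(-d / lambda) *
#' [0 < d <= cap]`, where `t` is the transcription-orientation offset from
#' the TSS and `d` the offset past the EAG, both evaluated at base centres.
#'
#' @param gene One row of a `GeneSet` gene table (or a one-row data frame
#'   with `start`, `end`, `strand`).
#' @param params Occupancy parameters (see [occupancy_params()]), optionally
#'   with amplitudes already scaled by a gene-activity multiplier.
#' @param flank Window extension on each side of the gene; must be at least
#'   `pause_cap_bp`.
#' @return Numeric vector over `[start - flank, end + flank)` (clipped at 0),
#'   with attribute `"genomic_start"` (0-based).
#' @export
occupancy_intensity <- function(gene, params, flank = NULL) {
  flank <- flank %||% params$pause_cap_bp
  .assert(flank >= params$pause_cap_bp, "flank must cover the pause cap")
  w_start <- max(gene$start - flank, 0)
  w_end <- gene$end + flank
  x <- seq(w_start, w_end - 1L)
  centre <- x + 0.5
  if (gene$strand == "+") {
    t_off <- centre - gene$start
    d_off <- centre - gene$end
  } else {
    t_off <- gene$end - centre
    d_off <- gene$start - centre
  }
  len <- gene$end - gene$start
  v <- rep(params$background_rate, length(x))
  v <- v + params$tss_amplitude *
    exp(-(t_off - params$tss_offset_bp)^2 / (2 * params$tss_sd_bp^2))
  v <- v + params$body_level * (t_off > 0 & t_off < len)
  pause <- d_off > 0 & d_off <= params$pause_cap_bp
  v[pause] <- v[pause] +
    params$pause_amplitude * exp(-d_off[pause] / params$pause_decay_bp)
  attr(v, "genomic_start") <- w_start
  v
}

# Genome-wide per-chromosome intensity vectors for a scenario truth table.
# mode "chip": all components; "mock": background only; "nascent": gene
# components only (no TSS cap on realism: engaged polymerase) plus
# nascent_background. Returns list(intensity, sense) where sense codes
# 0 = random strand, 1 = "+", 2 = "-" (used by nascent mode).
.genome_intensity <- function(genome, mode = c("chip", "mock", "nascent"),
                              nascent_background = 0) {
  mode <- match.arg(mode)
  g <- genome$genes$genes
  tr <- genome$truth[match(g$name, genome$truth$gene), ]
  bg <- if (mode == "nascent") nascent_background else tr$background_rate[1]
  intensity <- lapply(genome$chrom_sizes, function(n) rep(bg, n))
  sense <- lapply(genome$chrom_sizes, function(n) integer(n))
  for (i in seq_len(nrow(g))) {
    if (mode == "mock") break
    p <- list(
      tss_amplitude = tr$tss_amplitude[i], tss_offset_bp = tr$tss_offset_bp[i],
      tss_sd_bp = tr$tss_sd_bp[i], body_level = tr$body_level[i],
      pause_amplitude = tr$pause_amplitude[i],
      pause_decay_bp = tr$pause_decay_bp[i],
      pause_cap_bp = tr$pause_cap_bp[i], background_rate = 0
    )
    v <- occupancy_intensity(g[i, , drop = FALSE], p)
    ws <- attr(v, "genomic_start")
    ch <- g$chrom[i]
    idx <- seq.int(ws + 1L, length.out = length(v))
    keep <- idx <= length(intensity[[ch]])
    intensity[[ch]][idx[keep]] <- intensity[[ch]][idx[keep]] + v[keep]
    if (g$strand[i] == "+") {
      s0 <- g$start[i]; e0 <- min(g$end[i] + tr$pause_cap_bp[i],
                                  length(sense[[ch]]))
    } else {
      s0 <- max(g$start[i] - tr$pause_cap_bp[i], 0); e0 <- g$end[i]
    }
    sense[[ch]][(s0 + 1L):e0] <- if (g$strand[i] == "+") 1L else 2L
  }
  list(intensity = intensity, sense = sense)
}

#' Sample 32-bp tags from a per-base intensity model
#'
#' The total tag count is Poisson with mean `depth`; 5' start positions are
#' drawn proportionally to intensity. `chip` and `mock` tags get a random
#' strand; in `nascent` mode, tags starting inside a gene unit (body plus
#' downstream pause region) are assigned the gene's strand and background
#' tags a random strand.
#'
#' @param intensity Named list of per-chromosome intensity vectors, or a
#'   single vector (treated as chromosome `"chr1"`).
#' @param depth Expected total tag count.
#' @param read_len Tag length (default 32).
#' @param mode `"chip"`, `"mock"` or `"nascent"`.
#' @param seed RNG seed; identical seeds give identical tags.
#' @param sense Per-chromosome integer vectors (0 random, 1 `+`, 2 `-`) used
#'   in nascent mode; see `.genome_intensity()`.
#' @return Alignment data frame (`chrom`, `start`, `end`, `strand`), sorted.
#' @export
sample_reads <- function(intensity, depth, read_len = 32,
                         mode = c("chip", "mock", "nascent"), seed = 1L,
                         sense = NULL) {
  mode <- match.arg(mode)
  .assert(depth > 0, "depth must be positive")
  if (!is.list(intensity)) intensity <- list(chr1 = intensity)
  mass <- vapply(intensity, sum, numeric(1))
  .assert(sum(mass) > 0, "intensity has zero total mass")
  .with_seed(seed, {
    n_total <- rpois(1, depth)
    per_chrom <- if (length(mass) == 1L) n_total else
      as.integer(rmultinom(1, n_total, mass / sum(mass)))
    out <- vector("list", length(intensity))
    for (k in seq_along(intensity)) {
      n <- per_chrom[k]
      if (n == 0L) { out[[k]] <- NULL; next }
      vec <- intensity[[k]]
      pos0 <- sample.int(length(vec), n, replace = TRUE, prob = vec) - 1L
      strand <- if (mode == "nascent" && !is.null(sense)) {
        code <- sense[[k]][pos0 + 1L]
        s <- ifelse(code == 1L, "+", ifelse(code == 2L, "-", NA_character_))
        rnd <- which(is.na(s))
        s[rnd] <- sample(c("+", "-"), length(rnd), replace = TRUE)
        s
      } else {
        sample(c("+", "-"), n, replace = TRUE)
      }
      plus <- strand == "+"
      start <- ifelse(plus, pos0, pmax(pos0 - (read_len - 1L), 0))
      end <- ifelse(plus, pmin(pos0 + read_len, length(vec)), pos0 + 1L)
      out[[k]] <- data.frame(chrom = names(intensity)[k], start = start,
                             end = end, strand = strand,
                             stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    reads <- reads[order(reads$chrom, reads$start, reads$end, reads$strand), ]
    rownames(reads) <- NULL
    reads
  })
}

#' Apply a polyadenylation-inhibition-like condition to a truth table
#'
#' Scales the downstream pause amplitude by `gamma_downstream` and the TSS
#' amplitude by `delta_tss` on poly(A)+-type (`PA`) genes only; core-histone
#' (`H`) parameters are untouched.
#'
#' @param truth Truth table from [make_genome()].
#' @param gamma_downstream,delta_tss Positive scale factors.
#' @return The modified truth table, with attribute `"condition"` recording
#'   the factors.
#' @export
apply_condition <- function(truth, gamma_downstream = 2, delta_tss = 0.5) {
  .assert(gamma_downstream > 0 && delta_tss > 0, "factors must be positive")
  pa <- truth$pause_class == "PA"
  truth$pause_amplitude[pa] <- truth$pause_amplitude[pa] * gamma_downstream
  truth$tss_amplitude[pa] <- truth$tss_amplitude[pa] * delta_tss
  attr(truth, "condition") <- list(label = "cordycepin_like",
                                   gamma_downstream = gamma_downstream,
                                   delta_tss = delta_tss)
  truth
}

#' Simulate a full scenario: genome, truth and read tracks
#'
#' Generates the genome, then ChIP signal, matched-depth mock and (sense
#' stranded) nascent tracks. All randomness derives from `seed`.
#'
#' @param n_genes,class_mix,spacing_range,seed Passed to [make_genome()].
#' @param depth_per_gene Expected signal tags per gene (default 200).
#' @param mock_depth_per_gene Mock track depth (default matched, 200).
#' @param nascent_depth_per_gene Nascent track depth (default 100).
#' @param nascent_background Per-bp background intensity of the nascent
#'   track (default 0: no antisense transcription downstream of EAGs).
#' @param condition `"baseline"` or `"cordycepin_like"`.
#' @param gamma_downstream,delta_tss Condition factors (used when
#'   `condition = "cordycepin_like"`). Read depth scales with the ratio of
#'   total occupancy mass between conditions, modelling a constant
#'   immunoprecipitation recovery fraction, so mock-normalised signals
#'   compare across conditions on an absolute (qPCR-%input-like) scale.
#' @param ... Occupancy parameter overrides passed to [occupancy_params()].
#' @return List: `genome` (chrom_sizes, genes, truth, seed), `truth`
#'   (possibly condition-scaled), `reads` (list of alignment data frames:
#'   `signal`, `mock`, `nascent`), `expression` (data frame, 5 replicate
#'   columns), `depths`, `condition`.
#' @export
simulate_scenario <- function(n_genes = 200, class_mix = c(H = 0.5, PA = 0.5),
                              spacing_range = c(20000, 30000), seed = 1L,
                              depth_per_gene = 200,
                              mock_depth_per_gene = 200,
                              nascent_depth_per_gene = 100,
                              nascent_background = 0,
                              condition = c("baseline", "cordycepin_like"),
                              gamma_downstream = 2, delta_tss = 0.5, ...) {
  condition <- match.arg(condition)
  genome <- make_genome(n_genes = n_genes, class_mix = class_mix,
                        spacing_range = spacing_range, seed = seed, ...)
  truth <- genome$truth
  base_mass <- sum(vapply(.genome_intensity(genome, "chip")$intensity, sum,
                          numeric(1)))
  if (condition == "cordycepin_like")
    truth <- apply_condition(truth, gamma_downstream, delta_tss)
  genome$truth <- truth
  chip <- .genome_intensity(genome, "chip")
  mock <- .genome_intensity(genome, "mock")
  nascent <- .genome_intensity(genome, "nascent",
                               nascent_background = nascent_background)
  mass <- sum(vapply(chip$intensity, sum, numeric(1)))
  depth_scale <- mass / base_mass  # constant IP recovery fraction
  depths <- list(
    signal = n_genes * depth_per_gene * depth_scale,
    mock = n_genes * mock_depth_per_gene,
    nascent = n_genes * nascent_depth_per_gene
  )
  reads <- list(
    signal = sample_reads(chip$intensity, depths$signal, mode = "chip",
                          seed = .subseed(seed, 11)),
    mock = sample_reads(mock$intensity, depths$mock, mode = "mock",
                        seed = .subseed(seed, 12)),
    nascent = sample_reads(nascent$intensity, depths$nascent,
                           mode = "nascent", seed = .subseed(seed, 13),
                           sense = nascent$sense)
  )
  expression <- .with_seed(.subseed(seed, 14), {
    # expression spread is modelled independently of occupancy amplitudes
    base <- 100 * genome$truth$multiplier * exp(rnorm(n_genes, 0, 0.5))
    reps <- vapply(1:5, function(r) base * exp(rnorm(n_genes, 0, 0.1)),
                   numeric(n_genes))
    data.frame(gene = genome$truth$gene,
               setNames(as.data.frame(reps), paste0("rep", 1:5)))
  })
  list(genome = genome, truth = truth, reads = reads,
       expression = expression, depths = depths, condition = condition)
}

#' Simulate an untreated/treated condition pair on a shared genome
#'
#' @inheritParams simulate_scenario
#' @return List with `baseline` and `treated` scenarios (shared genome and
#'   gene-activity multipliers; independent read sampling) and the condition
#'   factors.
#' @export
simulate_condition_pair <- function(n_genes = 200,
                                    class_mix = c(H = 0.5, PA = 0.5),
                                    seed = 1L, depth_per_gene = 200,
                                    mock_depth_per_gene = 200,
                                    gamma_downstream = 2, delta_tss = 0.5,
                                    ...) {
  baseline <- simulate_scenario(
    n_genes = n_genes, class_mix = class_mix, seed = seed,
    depth_per_gene = depth_per_gene,
    mock_depth_per_gene = mock_depth_per_gene, condition = "baseline", ...)
  # same genome for both conditions: gene layout and activity multipliers
  # are shared, only the condition scaling and read sampling differ
  treated_truth <- apply_condition(baseline$genome$truth, gamma_downstream,
                                   delta_tss)
  genome_t <- baseline$genome
  genome_t$truth <- treated_truth
  chip_t <- .genome_intensity(genome_t, "chip")
  mass_u <- sum(vapply(.genome_intensity(baseline$genome, "chip")$intensity,
                       sum, numeric(1)))
  mass_t <- sum(vapply(chip_t$intensity, sum, numeric(1)))
  depth_t <- n_genes * depth_per_gene * mass_t / mass_u
  treated <- list(
    genome = genome_t, truth = treated_truth,
    reads = list(
      signal = sample_reads(chip_t$intensity, depth_t, mode = "chip",
                            seed = .subseed(seed, 21)),
      mock = sample_reads(.genome_intensity(genome_t, "mock")$intensity,
                          n_genes * mock_depth_per_gene, mode = "mock",
                          seed = .subseed(seed, 22))
    ),
    condition = "cordycepin_like"
  )
  list(baseline = baseline, treated = treated,
       gamma_downstream = gamma_downstream, delta_tss = delta_tss)
}

#' Write a simulated scenario to disk
#'
#' Writes `chrom.sizes`, `genes.bed` (BED12), one BED6 per read track,
#' `truth.tsv`, `expression.tsv` and a `scenario.yaml` capturing parameters
#' and seed.
#'
#' @param sc A scenario from [simulate_scenario()].
#' @param dir Output directory (created).
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- sc$genome$chrom_sizes
  write.table(data.frame(names(cs), unname(cs)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- sc$genome$genes$genes
  sizes <- vapply(seq_len(nrow(g)), function(i)
    paste(g$exon_ends[[i]] - g$exon_starts[[i]], collapse = ","), "")
  rel <- vapply(seq_len(nrow(g)), function(i)
    paste(g$exon_starts[[i]] - g$start[i], collapse = ","), "")
  bed12 <- data.frame(g$chrom, g$start, g$end, g$name, 0L, g$strand,
                      g$start, g$end, 0L, g$n_exons, sizes, rel)
  write.table(bed12, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (tr in names(sc$reads))
    write_alignments_bed(sc$reads[[tr]], file.path(dir, paste0(tr, ".bed")))
  .write_tsv(sc$truth, file.path(dir, "truth.tsv"))
  if (!is.null(sc$expression))
    .write_tsv(sc$expression, file.path(dir, "expression.tsv"))
  yaml::write_yaml(list(seed = sc$genome$seed, condition = sc$condition,
                        depths = sc$depths,
                        n_genes = nrow(g)),
                   file.path(dir, "scenario.yaml"))
  invisible(dir)
}
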