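#' Specification of a synthetic multi-slice SRT dataset
#'
#' Describes a dataset of spots on a regular 2-D lattice whose rows are
#' partitioned into contiguous horizontal bands (the spatial domains, meant
#' to mimic layered tissue such as cortex). Each domain owns a disjoint set
#' of marker genes whose log-mean is raised by `signal_strength`; counts are
#' Poisson around the gene mean, optionally zero-inflated by `dropout_p`.
#' Slices share the same domain layout; each slice can add a per-gene
#' additive shift on the log-mean scale (the classic location-shift batch
#' model) with standard deviation `batch_shift_sd`.
#'
#' @param grid_shape integer `(rows, cols)` of the lattice.
#' @param n_domains number of horizontal domain bands.
#' @param n_genes total genes; must be `>= n_domains * n_markers_per_domain`.
#' @param n_markers_per_domain marker genes per domain.
#' @param signal_strength log-fold elevation of marker genes, `> 0` for a
#'   signal.
#' @param base_mean baseline Poisson mean of every gene.
#' @param batch_shift_sd sd of the per-slice, per-gene log-mean shift.
#' @param dropout_p probability any count is zeroed after sampling.
#' @param n_slices number of slices.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return A `"synth_spec"` list.
#' @export
synth_spec <- function(grid_shape = c(20L, 25L),
                       n_domains = 5L,
                       n_genes = 200L,
                       n_markers_per_domain = 20L,
                       signal_strength = 1.5,
                       base_mean = 1.0,
                       batch_shift_sd = 0,
                       dropout_p = 0.1,
                       n_slices = 1L,
                       seed = 0L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               n_domains = as.integer(n_domains),
               n_genes = as.integer(n_genes),
               n_markers_per_domain = as.integer(n_markers_per_domain),
               signal_strength = signal_strength,
               base_mean = base_mean,
               batch_shift_sd = batch_shift_sd,
               dropout_p = dropout_p,
               n_slices = as.integer(n_slices),
               seed = as.integer(seed))
  if (length(spec$grid_shape) != 2L || any(spec$grid_shape < 1L))
    stop("grid_shape must be two positive integers")
  if (spec$grid_shape[1] < spec$n_domains)
    stop("need at least one lattice row per domain")
  if (spec$n_genes < spec$n_domains * spec$n_markers_per_domain)
    stop("not enough genes for the requested marker sets")
  if (spec$dropout_p < 0 || spec$dropout_p > 1)
    stop("dropout_p must be in [0, 1]")
  if (spec$base_mean <= 0) stop("base_mean must be > 0")
  if (spec$batch_shift_sd < 0) stop("batch_shift_sd must be >= 0")
  if (spec$n_slices < 1L) stop("need at least one slice")
  class(spec) <- "synth_spec"
  spec
}

#' Named preset dataset specifications
#'
#' `"easy"`: one 20 x 25 slice (500 spots), 5 domain bands, 200 genes with
#' 20 markers per domain at signal strength 1.5, no batch effect — a dataset
#' the pipeline should solve nearly perfectly. `"batchy"`: two such slices
#' with a per-gene log-mean batch shift of sd 1.0, creating a batch confound
#' that dominates naive dimensionality reduction.
#'
#' @param name `"easy"` or `"batchy"`.
#' @param seed seed to embed in the spec.
#' @return A `"synth_spec"`.
#' @export
synth_preset <- function(name = c("easy", "batchy"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
    easy = synth_spec(seed = seed),
    batchy = synth_spec(n_slices = 2L, batch_shift_sd = 1.0, seed = seed))
}

# lattice coordinates and banded domain labels for one slice
synth_layout <- function(spec) {
  R <- spec$grid_shape[1]; C <- spec$grid_shape[2]
  coords <- cbind(x = rep(seq_len(C), times = R),
                  y = rep(seq_len(R), each = C))
  band_sizes <- diff(round(seq(0, R, length.out = spec$n_domains + 1L)))
  row_domain <- rep(seq_len(spec$n_domains), times = band_sizes)
  domains <- row_domain[coords[, "y"]]
  list(coords = coords, domains = domains)
}

# noise-free per-spot gene mean matrix for one slice given its batch shift
synth_means <- function(spec, domains, batch_shift) {
  markers <- matrix(seq_len(spec$n_domains * spec$n_markers_per_domain),
                    nrow = spec$n_domains, byrow = TRUE)
  logmu <- matrix(log(spec$base_mean), length(domains), spec$n_genes)
  for (dmn in seq_len(spec$n_domains)) {
    rows <- domains == dmn
    logmu[rows, markers[dmn, ]] <- logmu[rows, markers[dmn, ]] +
      spec$signal_strength
  }
  exp(sweep(logmu, 2, batch_shift, "+"))
}

#' Generate a synthetic multi-slice SRT dataset
#'
#' @param spec a `"synth_spec"`.
#' @return A `"synth_data"` list: `slices` (list of `"raw_slice"`),
#'   `domains` (true domain label per pooled spot), `batches` (true slice
#'   index per pooled spot), `spec`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  layout <- synth_layout(spec)
  m <- nrow(layout$coords)
  gene_names <- paste0("g", seq_len(spec$n_genes) - 1L)
  slices <- vector("list", spec$n_slices)
  for (l in seq_len(spec$n_slices)) {
    shift <- if (spec$batch_shift_sd > 0)
      stats::rnorm(spec$n_genes, 0, spec$batch_shift_sd) else
      numeric(spec$n_genes)
    mu <- synth_means(spec, layout$domains, shift)
    counts <- matrix(stats::rpois(length(mu), mu), m, spec$n_genes)
    if (spec$dropout_p > 0)
      counts <- counts *
        matrix(stats::rbinom(length(mu), 1L, 1 - spec$dropout_p),
               m, spec$n_genes)
    storage.mode(counts) <- "double"
    colnames(counts) <- gene_names
    slices[[l]] <- new_raw_slice(counts, layout$coords,
                                 paste0("slice", l), gene_names)
  }
  structure(list(slices = slices,
                 domains = rep(layout$domains, spec$n_slices),
                 batches = rep(seq_len(spec$n_slices), each = m),
                 spec = spec),
            class = "synth_data")
}

#' Upper-bound recovery reference for a synthetic dataset
#'
#' Clusters the PCA of the *noise-free* per-spot mean matrix (pooled over
#' slices, without batch shifts) with the same Gaussian-mixture routine the
#' pipeline uses, and reports the ARI against the true domains. This is what
#' a method could at best recover if it removed all count noise and batch
#' effects; a tiny jitter breaks the exact degeneracy of identical rows.
#'
#' @param data a `"synth_data"`.
#' @param n_pcs PCs used for the reference clustering.
#' @return ARI in `[-1, 1]`.
#' @export
oracle_separability <- function(data, n_pcs = 10L) {
  spec <- data$spec
  layout <- synth_layout(spec)
  mu <- synth_means(spec, layout$domains, numeric(spec$n_genes))
  mu <- mu[rep(seq_len(nrow(mu)), spec$n_slices), , drop = FALSE]
  set.seed(spec$seed + 1L)
  jit <- mu + stats::rnorm(length(mu), 0, 1e-6 * (1 + stats::sd(mu)))
  n <- min(n_pcs, nrow(jit) - 1L, ncol(jit))
  scores <- pca_reduce(scale(jit, scale = FALSE), n)
  part <- gmm_cluster(scores, spec$n_domains, seed = spec$seed)
  ari(part$labels, data$domains)
}

#' Write a synthetic dataset to disk in the package's exchange formats
#'
#' One MTX + coordinate TSV pair per slice plus a pooled truth table
#' (`truth.tsv`: spot_id, slice_id, domain).
#'
#' @param data a `"synth_data"`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_synth <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in data$slices) write_slice(s, file.path(dir, s$slice_id))
  spot_ids <- unlist(lapply(data$slices, function(s) rownames(s$counts)),
                     use.names = FALSE)
  slice_ids <- rep(vapply(data$slices, `[[`, "", "slice_id"),
                   vapply(data$slices, function(s) nrow(s$counts), 1L))
  utils::write.table(
    data.frame(spot_id = spot_ids, slice_id = slice_ids,
               domain = data$domains),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
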