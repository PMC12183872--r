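#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline in one validated list: preprocessing
#' dimensionality, neighbor-graph sizes, augmentation rates, network layer
#' widths, contrastive temperatures, optimizer settings, and clustering
#' options. All fields have defaults so a run needs no mandatory arguments.
#'
#' @param n_pcs number of principal components kept as network input features.
#' @param k_spatial,k_expr neighbors per spot in the spatial and expression
#'   KNN graphs.
#' @param lambda_self weight of the self-connection when hybridizing an
#'   adjacency matrix, in `[0, 1]`.
#' @param noise_alpha standard deviation multiplier of the Gaussian feature
#'   noise added during augmentation.
#' @param mask_p probability that a feature entry is *kept* by the Bernoulli
#'   feature mask.
#' @param edge_keep_p probability that a stored graph edge survives edge
#'   masking.
#' @param d1,d,d2,d3,f hidden widths: encoder hidden (`d1`), bottleneck
#'   embedding (`d`), projection-head hidden (`d2`), attention hidden (`d3`),
#'   instance-projection output (`f`).
#' @param n_pseudo number of pseudo-cluster columns of the cluster projection
#'   head; `NULL` means "use `n_domains`".
#' @param tau_ins,tau_cls temperatures of the instance and cluster contrastive
#'   losses.
#' @param kappa weight of the instance loss in the total loss.
#' @param epochs,learning_rate Adam training length and step size.
#' @param prompt_lr_mult learning-rate multiplier applied to the two batch
#'   prompt embedding matrices. Adam's per-coordinate step is bounded by the
#'   learning rate, while the prompts must traverse offsets on the scale of
#'   the PC scores within the epoch budget, so they train faster than the
#'   network weights.
#' @param seed integer seed controlling initialization, augmentation and
#'   clustering.
#' @param n_domains number of spatial domains `K` requested from the final
#'   Gaussian-mixture clustering.
#' @param refinement_radius number of spatial nearest neighbors consulted by
#'   the majority-vote label refinement.
#' @param refine logical; apply the spatial refinement after clustering.
#' @return A named list of class `"spview_config"`.
#' @export
spview_config <- function(n_pcs = 30L,
                          k_spatial = 6L,
                          k_expr = 6L,
                          lambda_self = 0.3,
                          noise_alpha = 0.1,
                          mask_p = 0.9,
                          edge_keep_p = 0.9,
                          d1 = 128L, d = 64L, d2 = 64L, d3 = 32L, f = 32L,
                          n_pseudo = NULL,
                          tau_ins = 0.5,
                          tau_cls = 1.0,
                          kappa = 1.0,
                          epochs = 500L,
                          learning_rate = 1e-3,
                          prompt_lr_mult = 50,
                          seed = 0L,
                          n_domains = 5L,
                          refinement_radius = 6L,
                          refine = TRUE) {
  cfg <- list(
    n_pcs = as.integer(n_pcs),
    k_spatial = as.integer(k_spatial), k_expr = as.integer(k_expr),
    lambda_self = lambda_self,
    noise_alpha = noise_alpha, mask_p = mask_p, edge_keep_p = edge_keep_p,
    d1 = as.integer(d1), d = as.integer(d), d2 = as.integer(d2),
    d3 = as.integer(d3), f = as.integer(f),
    n_pseudo = if (is.null(n_pseudo)) as.integer(n_domains) else as.integer(n_pseudo),
    tau_ins = tau_ins, tau_cls = tau_cls, kappa = kappa,
    epochs = as.integer(epochs), learning_rate = learning_rate,
    prompt_lr_mult = prompt_lr_mult,
    seed = as.integer(seed),
    n_domains = as.integer(n_domains),
    refinement_radius = as.integer(refinement_radius),
    refine = isTRUE(refine)
  )
  validate_config(cfg)
  class(cfg) <- "spview_config"
  cfg
}

validate_config <- function(cfg) {
  probs <- c("lambda_self", "mask_p", "edge_keep_p")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1], got %s", p, format(v)))
  }
  dims <- c("n_pcs", "k_spatial", "k_expr", "d1", "d", "d2", "d3", "f",
            "n_pseudo", "n_domains", "refinement_radius", "epochs")
  for (p in dims) {
    v <- cfg[[p]]
    if (p == "epochs") {
      if (v < 0L) stop("'epochs' must be >= 0")
    } else if (v < 1L) stop(sprintf("'%s' must be >= 1, got %d", p, v))
  }
  for (p in c("tau_ins", "tau_cls")) {
    if (cfg[[p]] <= 0) stop(sprintf("'%s' must be > 0", p))
  }
  if (cfg$noise_alpha < 0) stop("'noise_alpha' must be >= 0")
  if (cfg$kappa < 0) stop("'kappa' must be >= 0")
  if (cfg$learning_rate <= 0) stop("'learning_rate' must be > 0")
  if (cfg$prompt_lr_mult <= 0) stop("'prompt_lr_mult' must be > 0")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; keys absent from the file fall back to the
#' defaults of [spview_config()].
#'
#' @param path path to a YAML key-value file.
#' @return A `"spview_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(spview_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(spview_config, vals)
}

#' @export
print.spview_config <- function(x, ...) {
  cat("spview run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
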