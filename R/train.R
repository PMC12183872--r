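adam_init <- function(state) {
  list(m = lapply(state, function(p) array(0, dim(p))),
       v = lapply(state, function(p) array(0, dim(p))),
       t = 0L)
}

adam_step <- function(state, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, frozen = character(), lr_mult = NULL) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(state)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    lr_nm <- lr * (if (!is.null(lr_mult) && nm %in% names(lr_mult))
      lr_mult[[nm]] else 1)
    state[[nm] ] <- state[[nm]] -
      lr_nm * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(state = state, opt = opt)
}

#' Train the model on a multi-view graph
#'
#' Full-graph training: every epoch draws fresh feature/edge augmentations,
#' runs the forward pass, evaluates the (ablation-dependent) loss, and takes
#' one Adam step on all parameters. The single seed in `cfg` controls
#' parameter initialization and the augmentation stream, so a run is
#' reproducible end to end.
#'
#' Ablation modes: `"no_instance"` drops the instance contrastive term,
#' `"no_cluster"` the cluster contrastive term, `"no_both"` trains the plain
#' graph autoencoder, and `"no_prompting"` freezes both batch prompt
#' embeddings at zero.
#'
#' @param features a `"feature_matrix"` from [preprocess_slices()].
#' @param graph a `"multiview_graph"`.
#' @param cfg a `"spview_config"`.
#' @param ablation one of `"full"`, `"no_instance"`, `"no_cluster"`,
#'   `"no_both"`, `"no_prompting"`.
#' @param verbose print per-epoch loss components.
#' @return list with `state` (trained `"model_state"`), `log` (a
#'   `"train_log"`: per-epoch loss breakdowns, seed, ablation mode), `E`
#'   (batch indicator), `cfg`.
#' @export
fit <- function(features, graph, cfg = spview_config(), ablation = "full",
                verbose = FALSE) {
  ablation <- match.arg(ablation,
                        c("full", "no_instance", "no_cluster", "no_both",
                          "no_prompting"))
  X <- features$X
  L <- length(features$m_per_slice)
  E <- batch_design(features$spot_slice_index, L)
  set.seed(cfg$seed)
  state <- init_model(ncol(X), L, cfg)
  opt <- adam_init(state)
  frozen <- if (ablation == "no_prompting" || L == 1L) c("B1", "B2") else character()
  use_ins <- !(ablation %in% c("no_instance", "no_both"))
  use_cls <- !(ablation %in% c("no_cluster", "no_both"))

  history <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    out <- forward_pass(state, X, graph, E, cfg, training = TRUE)
    d_out <- list()

    rec <- recon_loss(X, out$X_hat, grad = TRUE)
    d_out$dX_hat <- rec$dX_hat

    parts <- list(L_rec = rec$value, L_ins = 0,
                  L_cls_spa = 0, L_cls_expr = 0,
                  L_reg_spa = 0, L_reg_expr = 0)
    if (use_ins) {
      ins <- instance_loss(out$H_spa, out$H_expr, cfg$tau_ins, grad = TRUE,
                           strict = FALSE)
      parts$L_ins <- ins$value
      d_out$dH_spa <- cfg$kappa * ins$dH_spa
      d_out$dH_expr <- cfg$kappa * ins$dH_expr
    }
    if (use_cls) {
      cls <- cluster_loss(out$Q_spa, out$Q_expr, cfg$tau_cls, grad = TRUE,
                          strict = FALSE)
      parts[c("L_cls_spa", "L_cls_expr", "L_reg_spa", "L_reg_expr")] <-
        cls[c("L_cls_spa", "L_cls_expr", "L_reg_spa", "L_reg_expr")]
      d_out$dQ_spa <- cls$dQ_spa
      d_out$dQ_expr <- cls$dQ_expr
    }
    lb <- total_loss(parts, cfg$kappa, ablation)
    if (!is.finite(lb$total)) {
      comp <- c(L_rec = parts$L_rec, L_ins = parts$L_ins,
                L_cls_spa = parts$L_cls_spa, L_cls_expr = parts$L_cls_expr)
      bad <- names(comp)[!is.finite(comp)]
      stop(sprintf("non-finite loss at epoch %d (component: %s)", ep,
                   paste(bad, collapse = ", ")))
    }
    history[[ep]] <- lb
    if (verbose)
      message(sprintf(
        "epoch %4d  total %.5f  rec %.5f  cls %.5f  ins %.5f",
        ep, lb$total, parts$L_rec, parts$L_cls_spa + parts$L_cls_expr,
        parts$L_ins))

    grads <- backward_pass(state, out, d_out)
    stepped <- adam_step(state, grads, opt, cfg$learning_rate, frozen = frozen,
                         lr_mult = list(B1 = cfg$prompt_lr_mult,
                                        B2 = cfg$prompt_lr_mult))
    state <- stepped$state
    opt <- stepped$opt
  }

  log <- structure(list(history = history, epochs = cfg$epochs,
                        seed = cfg$seed, ablation = ablation),
                   class = "train_log")
  list(state = state, log = log, E = E, cfg = cfg,
       features = features, graph = graph)
}

#' Extract inference embeddings
#'
#' Runs a deterministic forward pass (augmentation disabled) and returns the
#' fused bottleneck embeddings `Z`. The per-slice prompt `B1` is still
#' subtracted from the input — that is where the batch correction lives — but
#' `B2` is *not* re-added, so the embeddings are batch-free.
#'
#' @param fitted the list returned by [fit()] (or a `"model_state"` plus
#'   explicit `features`/`graph`/`E`).
#' @param features,graph,E optional overrides.
#' @return m x d embedding matrix.
#' @export
extract_embeddings <- function(fitted, features = NULL, graph = NULL, E = NULL) {
  state <- if (inherits(fitted, "model_state")) fitted else fitted$state
  cfg <- if (is.null(fitted$cfg)) spview_config() else fitted$cfg
  if (is.null(E)) E <- fitted$E
  if (is.null(features)) features <- fitted$features
  if (is.null(graph)) graph <- fitted$graph
  X <- features$X
  out <- forward_pass(state, X, graph, E, cfg, training = FALSE)
  Z <- out$Z
  rownames(Z) <- features$spot_ids
  Z
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain-text JSON archive holding every parameter tensor
#' keyed by name plus the run configuration.
#'
#' @param fitted result of [fit()].
#' @param path output file.
#' @export
save_checkpoint <- function(fitted, path) {
  obj <- list(state = lapply(fitted$state, function(m) list(dim = dim(m),
                                                            x = as.vector(m))),
              cfg = unclass(fitted$cfg))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- lapply(obj$state, function(e) matrix(e$x, e$dim[1], e$dim[2]))
  class(state) <- "model_state"
  cfg <- do.call(spview_config, obj$cfg[names(obj$cfg) %in%
                                          names(formals(spview_config))])
  list(state = state, cfg = cfg)
}
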