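# Feed-forward engine for the two neural models: a plain deep net (depth x
# layer_size hidden layers over the full feature vector) and the forked net
# (one affine+ReLU entry branch per feature block, concatenated into a trunk
# whose widths halve geometrically with a floor of 16, ending in one linear
# unit). Training: squared-error loss, Adam with optional decoupled weight
# decay, mini-batches of 32, inverted dropout when enabled. Everything runs
# on plain BLAS matrix ops, so a fixed seed gives run-to-run reproducible
# fits on CPU.
#
# Input representation: the assembled matrix is z-scored column-wise, which
# maps rare indicator columns onto a handful of extreme values (|z| > 20 for
# a column observed once or twice in training). Gradient training is
# destabilized by such inputs, so the net trainers fit a per-column remap
# that returns two-level (indicator) columns to {0, 1} while leaving
# continuous columns z-scored; the remap is stored with the fit and applied
# identically at prediction time.

relu <- function(x) (x > 0) * x

init_affine <- function(n_in, n_out, zero = FALSE) {
  w <- if (zero) matrix(0, n_in, n_out) else
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  list(W = w, b = matrix(0, 1, n_out))
}

trunk_widths <- function(concat_width, depth, floor_width = 16L) {
  w <- integer(depth)
  cur <- concat_width
  for (i in seq_len(depth)) {
    cur <- max(floor_width, floor(cur / 2))
    w[i] <- cur
  }
  w
}

#' Specify a forked network
#'
#' @param branch_widths named integer vector of per-branch layer sizes; names
#'   must match the seven feature-block entry points (see
#'   [forked_branch_names()]) or, for toy schemas, the block-group names in
#'   use.
#' @param depth trunk depth (number of hidden trunk layers).
#' @param dropout dropout rate in (0, 1).
#' @param use_dropout logical; dropout applied only when TRUE.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient;
#'   0 disables.
#' @return object of class `cpp_forked_spec`.
#' @export
forked_net_spec <- function(branch_widths, depth = 7, dropout = 0.9,
                            use_dropout = FALSE, learning_rate = 1e-4,
                            epochs = 170, weight_decay = 0) {
  if (any(branch_widths < 1)) abort("branch widths must be positive", "config_error")
  if (!(dropout > 0 && dropout < 1)) abort("dropout must be in (0,1)", "config_error")
  structure(list(branch_widths = branch_widths, depth = as.integer(depth),
                 dropout = dropout, use_dropout = isTRUE(use_dropout),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay),
            class = "cpp_forked_spec")
}

#' The seven forked-net entry-point names on the full schema
#' @return character vector.
#' @export
forked_branch_names <- function() names(forked_block_groups())

# ---- generic layered net -----------------------------------------------
# A net is a list of layers; each layer: affine params + activation flag.
# The forked net is expressed as a first "parallel" layer over column groups.

build_plain_net <- function(n_in, depth, layer_size, zero = FALSE) {
  sizes <- c(n_in, rep(layer_size, depth), 1L)
  lapply(seq_len(length(sizes) - 1L), function(i)
    c(init_affine(sizes[i], sizes[i + 1L], zero),
      list(activation = i < length(sizes) - 1L)))
}

build_forked_net <- function(group_cols, branch_widths, depth, zero = FALSE) {
  branches <- lapply(names(group_cols), function(g)
    c(init_affine(length(group_cols[[g]]), branch_widths[[g]], zero),
      list(cols = group_cols[[g]])))
  names(branches) <- names(group_cols)
  concat <- sum(unlist(branch_widths[names(group_cols)]))
  widths <- trunk_widths(concat, depth)
  sizes <- c(concat, widths, 1L)
  trunk <- lapply(seq_len(length(sizes) - 1L), function(i)
    c(init_affine(sizes[i], sizes[i + 1L], zero),
      list(activation = i < length(sizes) - 1L)))
  list(branches = branches, trunk = trunk)
}

#' Parameter count of a forked network
#'
#' Affine arithmetic: each branch `(d_g + 1) * w_g`; trunk layers
#' `(n_in + 1) * n_out` down the halving widths; final linear unit included.
#'
#' @param group_sizes named integer vector of input widths per branch.
#' @param spec a `cpp_forked_spec`.
#' @return integer parameter count.
#' @export
forked_param_count <- function(group_sizes, spec) {
  bw <- spec$branch_widths[names(group_sizes)]
  n <- sum((unlist(group_sizes) + 1) * unlist(bw))
  sizes <- c(sum(unlist(bw)), trunk_widths(sum(unlist(bw)), spec$depth), 1L)
  n + sum((sizes[-length(sizes)] + 1) * sizes[-1])
  }

# forward pass through a stack of affine(+ReLU) layers; returns activations
stack_forward <- function(layers, x, dropout = 0, rng_dropout = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  masks <- vector("list", length(layers))
  acts[[1]] <- x
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    z <- acts[[i]] %*% l$W + matrix(l$b, nrow(x), ncol(l$W), byrow = TRUE)
    a <- if (isTRUE(l$activation)) relu(z) else z
    if (isTRUE(l$activation) && rng_dropout && dropout > 0) {
      m <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
      a <- a * m
      masks[[i]] <- m
    }
    acts[[i + 1L]] <- a
  }
  list(acts = acts, masks = masks)
}

# gradient of a stack given upstream gradient on its output
stack_backward <- function(layers, fw, grad_out) {
  grads <- vector("list", length(layers))
  g <- grad_out
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    a_out <- fw$acts[[i + 1L]]
    if (isTRUE(l$activation)) {
      if (!is.null(fw$masks[[i]])) g <- g * fw$masks[[i]]
      g <- g * (a_out > 0)
    }
    grads[[i]] <- list(W = crossprod(fw$acts[[i]], g),
                       b = matrix(colSums(g), 1))
    g <- g %*% t(l$W)
  }
  list(grads = grads, grad_in = g)
}

adam_state <- function(params) lapply(params, function(p)
  list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))

adam_update <- function(layer, grad, st, lr, t, wd = 0,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$mW <- b1 * st$mW + (1 - b1) * grad$W
  st$vW <- b2 * st$vW + (1 - b2) * grad$W^2
  st$mb <- b1 * st$mb + (1 - b1) * grad$b
  st$vb <- b2 * st$vb + (1 - b2) * grad$b^2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  layer$W <- layer$W - lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
  if (wd > 0) layer$W <- layer$W * (1 - lr * wd)  # decoupled decay
  layer$b <- layer$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
  list(layer = layer, state = st)
}

# per-column remap returning two-level columns to {0,1}; continuous columns
# pass through. Fitted on the training matrix only.
fit_binary_remap <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  two <- hi > lo & apply(x, 2, function(col) length(unique(col)) <= 2L)
  list(cols = which(two), lo = lo[two], range = (hi - lo)[two])
}

apply_binary_remap <- function(map, x) {
  if (!length(map$cols)) return(x)
  x[, map$cols] <- sweep(sweep(x[, map$cols, drop = FALSE], 2, map$lo),
                         2, map$range, "/")
  x
}

#' Forward pass of a forked network
#'
#' @param net a built forked network (from training, or
#'   [forked_forward()]'s `spec` interface below).
#' @param x numeric matrix whose columns cover every branch's column set.
#' @param dropout,rng_dropout training-time dropout controls (internal).
#' @return list with `pred` (n x 1 matrix) and cached activations.
#' @keywords internal
forked_forward_net <- function(net, x, dropout = 0, rng_dropout = FALSE) {
  branch_fw <- lapply(net$branches, function(b) {
    z <- x[, b$cols, drop = FALSE] %*% b$W + matrix(b$b, nrow(x), ncol(b$W), byrow = TRUE)
    a <- relu(z)
    m <- NULL
    if (rng_dropout && dropout > 0) {
      m <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
      a <- a * m
    }
    list(z = z, a = a, mask = m)
  })
  concat <- do.call(cbind, lapply(branch_fw, `[[`, "a"))
  trunk_fw <- stack_forward(net$trunk, concat, dropout, rng_dropout)
  list(pred = trunk_fw$acts[[length(trunk_fw$acts)]],
       branch_fw = branch_fw, concat = concat, trunk_fw = trunk_fw)
}

#' Single-record forward pass through a forked-net specification
#'
#' Builds (or reuses) the wiring implied by `spec` over the given feature
#' blocks and evaluates the prediction. Primarily a structural interface;
#' training uses the same machinery internally.
#'
#' @param spec a `cpp_forked_spec` whose branch names match `block_inputs`.
#' @param block_inputs named list of numeric vectors, one per feature block.
#' @param net optional pre-built network (e.g. zero-initialized); built fresh
#'   from `spec` when NULL.
#' @param zero_init initialize all weights to zero (analytic checks).
#' @return single numeric prediction.
#' @export
forked_forward <- function(spec, block_inputs, net = NULL, zero_init = FALSE) {
  widths <- vapply(block_inputs, length, integer(1))
  miss <- setdiff(names(block_inputs), names(spec$branch_widths))
  if (length(miss))
    abort(paste0("no branch width for block: ", miss[1]), "shape_error")
  x <- matrix(unlist(block_inputs), nrow = 1)
  start <- cumsum(c(1, widths[-length(widths)]))
  group_cols <- lapply(seq_along(widths), function(i) start[i]:(start[i] + widths[i] - 1L))
  names(group_cols) <- names(block_inputs)
  if (is.null(net))
    net <- build_forked_net(group_cols, spec$branch_widths, spec$depth, zero = zero_init)
  for (g in names(group_cols))
    if (nrow(net$branches[[g]]$W) != widths[[g]])
      abort(sprintf("block '%s' width %d does not match branch input %d",
                    g, widths[[g]], nrow(net$branches[[g]]$W)), "shape_error")
  as.numeric(forked_forward_net(net, x)$pred)
}

# ---- training loops ----------------------------------------------------

train_plain_net <- function(x, y, depth, layer_size, learning_rate, epochs,
                            use_dropout = FALSE, dropout_rate = 0.3,
                            weight_decay = 0, average_epochs = 0,
                            batch_size = 32L, seed = 1L) {
  set.seed(seed)
  net <- build_plain_net(ncol(x), depth, layer_size)
  st <- adam_state(net)
  n <- nrow(x)
  t <- 0
  curve <- numeric(epochs)
  avg <- NULL; n_avg <- 0
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- stack_forward(net, x[idx, , drop = FALSE],
                          dropout = if (use_dropout) dropout_rate else 0,
                          rng_dropout = use_dropout)
      pred <- fw$acts[[length(fw$acts)]]
      g <- 2 * (pred - y[idx]) / length(idx)
      bw <- stack_backward(net, fw, g)
      t <- t + 1
      for (i in seq_along(net)) {
        up <- adam_update(net[[i]], bw$grads[[i]], st[[i]], learning_rate, t,
                          wd = weight_decay)
        net[[i]]$W <- up$layer$W; net[[i]]$b <- up$layer$b
        st[[i]] <- up$state
      }
    }
    # running mean of the weights over the final average_epochs epochs
    if (average_epochs > 0 && e > epochs - average_epochs) {
      n_avg <- n_avg + 1
      if (is.null(avg)) avg <- net
      else for (i in seq_along(net)) {
        avg[[i]]$W <- avg[[i]]$W + (net[[i]]$W - avg[[i]]$W) / n_avg
        avg[[i]]$b <- avg[[i]]$b + (net[[i]]$b - avg[[i]]$b) / n_avg
      }
    }
    pred_all <- stack_forward(net, x)$acts[[length(net) + 1L]]
    curve[e] <- mean((pred_all - y)^2)
  }
  list(net = if (is.null(avg)) net else avg, loss_curve = curve)
}

train_forked_net <- function(x, y, group_cols, spec, batch_size = 32L, seed = 1L) {
  set.seed(seed)
  net <- build_forked_net(group_cols, spec$branch_widths, spec$depth)
  st_b <- adam_state(net$branches)
  st_t <- adam_state(net$trunk)
  n <- nrow(x)
  t <- 0
  dr <- if (spec$use_dropout) spec$dropout else 0
  curve <- numeric(spec$epochs)
  widths <- vapply(net$branches, function(b) ncol(b$W), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  for (e in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- forked_forward_net(net, x[idx, , drop = FALSE], dr, spec$use_dropout)
      g <- 2 * (fw$pred - y[idx]) / length(idx)
      bw <- stack_backward(net$trunk, fw$trunk_fw, g)
      t <- t + 1
      for (i in seq_along(net$trunk)) {
        up <- adam_update(net$trunk[[i]], bw$grads[[i]], st_t[[i]], spec$learning_rate, t,
                          wd = spec$weight_decay %||% 0)
        net$trunk[[i]]$W <- up$layer$W; net$trunk[[i]]$b <- up$layer$b
        st_t[[i]] <- up$state
      }
      for (k in seq_along(net$branches)) {
        b <- net$branches[[k]]
        gb <- bw$grad_in[, starts[k]:ends[k], drop = FALSE]
        if (!is.null(fw$branch_fw[[k]]$mask)) gb <- gb * fw$branch_fw[[k]]$mask
        gb <- gb * (fw$branch_fw[[k]]$z > 0)
        grad <- list(W = crossprod(x[idx, b$cols, drop = FALSE], gb),
                     b = matrix(colSums(gb), 1))
        up <- adam_update(b, grad, st_b[[k]], spec$learning_rate, t,
                          wd = spec$weight_decay %||% 0)
        net$branches[[k]]$W <- up$layer$W; net$branches[[k]]$b <- up$layer$b
        st_b[[k]] <- up$state
      }
    }
    curve[e] <- mean((forked_forward_net(net, x)$pred - y)^2)
  }
  list(net = net, loss_curve = curve)
}

# map schema blocks (restricted to surviving columns) onto branch groups
forked_group_cols <- function(colnames_now, schema) {
  blocks <- schema_block_of(schema)
  names(blocks) <- schema_colnames(schema)
  groups <- forked_block_groups()
  out <- lapply(groups, function(bl)
    which(colnames_now %in% names(blocks)[blocks %in% bl]))
  out[vapply(out, length, integer(1)) > 0]
}
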