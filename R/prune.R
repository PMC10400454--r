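# Structured channel pruning driven by batch-norm scaling factors: L1
# sparsity training pushes unimportant gamma toward zero, channels are
# ranked globally by |gamma|, the cheapest coupled channel groups are
# removed up to the requested ratio, and each removed channel's constant
# contribution (its post-activation beta) is folded into the consumers so
# that removing an exactly-zero-gamma channel preserves the function.

#' Sparsity-training configuration
#'
#' Defaults follow the compression recipe: penalty 0.001, learning rate
#' 1e-4, batch size 16, 100 iterations (epochs over the sparsity set).
#'
#' @param penalty L1 penalty factor lambda on BN gamma (`>= 0`).
#' @param learning_rate SGD learning rate.
#' @param batch_size minibatch size.
#' @param iterations training epochs.
#' @export
sparsity_config <- function(penalty = 0.001, learning_rate = 1e-4,
                            batch_size = 16L, iterations = 100L) {
  if (penalty < 0) stop("sparsity_config: penalty must be >= 0")
  structure(list(penalty = penalty, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations)),
            class = "sparsity_config")
}

#' L1 sparsity penalty on scaling factors
#'
#' `lambda * sum(|gamma|)`; the total training loss is the detection loss
#' plus this term, whose subgradient `lambda * sign(gamma)` is added to the
#' gamma gradients during sparsity training.
#'
#' @param scales vector of BN gamma values.
#' @param lambda penalty factor (`>= 0`).
#' @return the penalty value.
#' @export
sparsity_penalty <- function(scales, lambda) {
  if (lambda < 0) stop("sparsity_penalty: lambda must be >= 0")
  lambda * sum(abs(scales))
}

#' Sparsity training
#'
#' Continues training from the current weights with the L1 constraint on
#' every prunable batch-norm gamma, shrinking unimportant channels' scaling
#' factors toward zero ahead of pruning.
#'
#' @param net an initialized `pest_net`.
#' @param samples training samples.
#' @param cfg a [sparsity_config()].
#' @param seed RNG seed.
#' @param verbose print progress.
#' @return list with `net` and `history`.
#' @export
sparse_train <- function(net, samples, cfg = sparsity_config(), seed = 1L,
                         verbose = FALSE) {
  r <- train_detector(net, samples, cfg$iterations, cfg$batch_size,
                      cfg$learning_rate, sparsity_lambda = cfg$penalty,
                      seed = seed, phase = "sparse", verbose = verbose)
  list(net = r$net, history = r$history)
}

# ---- channel coupling --------------------------------------------------

# Union-find over channel slots. Channels that must live or die together
# (residual adds, depthwise 1:1 maps, ASFF blends, focus copies) share a
# group; groups touching an unprunable anchor (input, stem, biased output
# convolutions, BN layers flagged unprunable) are tainted and never pruned.
channel_groups <- function(net) {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)
  env$taint <- logical(0)
  ng <- function(n, taint = FALSE) {
    at <- length(env$parent)
    ids <- at + seq_len(n)
    env$parent[ids] <- ids
    env$taint[ids] <- taint
    ids
  }
  find <- function(i) {
    while (env$parent[i] != i) {
      env$parent[i] <- env$parent[env$parent[i]]
      i <- env$parent[i]
    }
    i
  }
  uni <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) {
      env$parent[rb] <- ra
      env$taint[ra] <- env$taint[ra] || env$taint[rb]
    }
    ra
  }
  gl <- list()
  for (l in net$layers) {
    gl[[l$name]] <- switch(l$type,
      input = ng(l$channels, taint = TRUE),
      conv = ng(l$cout, taint = isTRUE(l$bias)),
      dwconv = gl[[l$inputs]],
      bn = {
        g <- gl[[l$inputs]]
        if (!isTRUE(l$prunable)) {
          for (i in g) env$taint[find(i)] <- TRUE
        }
        g
      },
      act = gl[[l$inputs]],
      maxpool = gl[[l$inputs]],
      upsample = gl[[l$inputs]],
      eca = gl[[l$inputs]],
      focus = rep(gl[[l$inputs]], 4L),
      concat = unlist(lapply(l$inputs, function(nm) gl[[nm]])),
      add = {
        g1 <- gl[[l$inputs[1]]]
        g2 <- gl[[l$inputs[2]]]
        vapply(seq_along(g1), function(ch) uni(g1[ch], g2[ch]), 1L)
      },
      asff = {
        gs <- lapply(l$inputs[1:3], function(nm) gl[[nm]])
        vapply(seq_along(gs[[1]]),
               function(ch) uni(uni(gs[[1]][ch], gs[[2]][ch]), gs[[3]][ch]), 1L)
      },
      stop("channel_groups: unknown layer type ", l$type)
    )
  }
  groups <- lapply(gl, function(g) vapply(g, find, 1L))
  list(groups = groups, taint = env$taint)
}

bn_gamma_table <- function(net, cg = channel_groups(net)) {
  rows <- list()
  li <- 0L
  for (l in net$layers) {
    li <- li + 1L
    if (l$type != "bn" || !isTRUE(l$prunable)) next
    g <- cg$groups[[l$name]]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l$name, layer_index = li, channel = seq_len(l$c),
      gamma = l$gamma, root = g, taint = cg$taint[g],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("rank_channels: network has no prunable BN layers")
  do.call(rbind, rows)
}

#' Globally rank channels by |gamma|
#'
#' All prunable batch-norm scaling factors sorted by ascending absolute
#' value with a stable (layer index, channel index) tie-break.
#'
#' @param net an initialized `pest_net`.
#' @return `data.frame` with `layer`, `channel`, `gamma`, `abs_gamma`,
#'   sorted ascending.
#' @export
rank_channels <- function(net) {
  tab <- bn_gamma_table(net)
  tab$abs_gamma <- abs(tab$gamma)
  tab <- tab[order(tab$abs_gamma, tab$layer_index, tab$channel), ]
  rownames(tab) <- NULL
  tab[, c("layer", "channel", "gamma", "abs_gamma")]
}

#' Build a channel pruning plan
#'
#' Ranks coupled channel groups by their importance score (the largest
#' member |gamma|: a group is removable only when every coupled channel is
#' unimportant — the intersection rule) and marks the cheapest groups for
#' removal until the requested fraction of the original prunable channels
#' is reached, never emptying a layer (at least one channel always
#' survives). The ratio is global and anchored to the unpruned network, so
#' re-planning an already-pruned network at the same ratio removes nothing.
#'
#' @param net an initialized `pest_net`.
#' @param ratio target fraction of prunable channels to remove, in
#'   `[0, 1)`.
#' @param layer_floor minimum fraction of each layer's channels that must
#'   survive (always at least one channel). A global |gamma| threshold
#'   otherwise concentrates removal on whole layers whose scales happen to
#'   sit low — e.g. freshly trained neck layers against a frozen backbone —
#'   and strangles them; slimming practice keeps a per-layer reserve.
#' @return a `pruning_plan`: per-BN keep masks, threshold `gamma_star`
#'   (largest removed score), requested and achieved fractions.
#' @export
build_pruning_plan <- function(net, ratio, layer_floor = 0.2) {
  if (ratio < 0 || ratio >= 1) stop("build_pruning_plan: ratio must be in [0, 1)")
  if (layer_floor < 0 || layer_floor >= 1) {
    stop("build_pruning_plan: layer_floor must be in [0, 1)")
  }
  cg <- channel_groups(net)
  tab <- bn_gamma_table(net, cg)
  prunable_now <- sum(!tab$taint)
  prunable_total <- net$prunable_total %||% prunable_now
  target <- floor(ratio * prunable_total)
  need <- target - net$pruned_removed
  ptab <- tab[!tab$taint, , drop = FALSE]
  # group table: score = max |gamma|, stable provenance tie-break
  sp <- split(ptab, ptab$root)
  groups <- data.frame(
    root = as.integer(names(sp)),
    score = vapply(sp, function(d) max(abs(d$gamma)), 0),
    size = vapply(sp, nrow, 0L),
    li = vapply(sp, function(d) min(d$layer_index), 0L),
    ch = vapply(sp, function(d) d$channel[which.min(d$layer_index)], 0L))
  groups <- groups[order(groups$score, groups$li, groups$ch), ]
  layer_channels <- vapply(split(tab$channel, tab$layer), length, 0L)
  kept <- layer_channels
  floor_cnt <- stats::setNames(
    pmax(1L, as.integer(ceiling(layer_floor * layer_channels))),
    names(layer_channels))
  removed_roots <- integer(0)
  removed <- 0L
  if (need > 0) {
    for (i in seq_len(nrow(groups))) {
      if (removed >= need) break
      g <- groups[i, ]
      mem <- sp[[as.character(g$root)]]
      percnt <- table(mem$layer)
      if (any(kept[names(percnt)] - as.integer(percnt) <
              floor_cnt[names(percnt)])) next # per-layer floor
      if (abs(removed + g$size - need) > abs(removed - need)) break
      removed_roots <- c(removed_roots, g$root)
      removed <- removed + g$size
      kept[names(percnt)] <- kept[names(percnt)] - as.integer(percnt)
    }
  }
  keep <- lapply(split(tab, tab$layer), function(d) {
    k <- rep(TRUE, max(d$channel))
    k[d$channel[d$root %in% removed_roots]] <- FALSE
    k
  })
  structure(list(
    keep = keep,
    removed_roots = removed_roots,
    groups = cg$groups,
    ratio = ratio,
    gamma_star = if (removed) max(groups$score[groups$root %in% removed_roots]) else 0,
    removed = removed,
    prunable_total = prunable_total,
    achieved = (net$pruned_removed + removed) / prunable_total,
    layer_names = names(net$layers)
  ), class = "pruning_plan")
}

#' @export
print.pruning_plan <- function(x, ...) {
  cat("<pruning_plan> requested ", x$ratio, " achieved ",
      round(x$achieved, 4), " (", x$removed, " channels removed, gamma* = ",
      signif(x$gamma_star, 4), ")\n", sep = "")
  invisible(x)
}

#' Serialize a pruning plan to JSON
#'
#' @param plan a `pruning_plan`.
#' @param path output file.
#' @export
write_pruning_plan <- function(plan, path) {
  jsonlite::write_json(list(ratio = plan$ratio, achieved = plan$achieved,
                            gamma_star = plan$gamma_star, keep = plan$keep),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a pruning plan
#'
#' Removes the planned channels from each batch-norm layer, from the
#' producing convolution's output filters and from every consumer's input
#' slices. The constant that a removed channel would have contributed (its
#' post-activation `beta`) is folded into consumers: into the bias of
#' biased 1x1 convolutions, into the running mean of the following batch
#' norm for unbiased 1x1 convolutions, and as a cached spatial correction
#' map (the removed kernel slices convolved with the constant) for larger
#' kernels, which is exact under zero padding. Constants that pass an ECA
#' gate are folded dynamically with the per-image gate value. Removal of a
#' channel whose gamma is exactly zero therefore preserves the function to
#' float precision on non-attention paths.
#'
#' @param net the `pest_net` the plan was built for.
#' @param plan a [build_pruning_plan()] result.
#' @return the pruned `pest_net` (strictly fewer learnable parameters
#'   whenever any channel was removed).
#' @export
apply_pruning <- function(net, plan) {
  if (!identical(plan$layer_names, names(net$layers))) {
    stop("apply_pruning: plan was built for a different network")
  }
  if (!length(plan$removed_roots)) return(net)
  rmset <- plan$removed_roots
  G <- plan$groups
  keeps <- list()
  cvals <- list()   # constant value of removed channels (NA = kept)
  cdyn <- list()    # "" static, else source eca layer name
  cpos <- list()    # index into the source eca's removed-slot list
  pending <- list() # scalar shifts to fold into the next BN's running mean
  out <- net
  for (l in net$layers) {
    nm <- l$name
    g <- G[[nm]]
    switch(l$type,
      input = {
        keeps[[nm]] <- rep(TRUE, l$channels)
        cvals[[nm]] <- rep(NA_real_, l$channels)
        cdyn[[nm]] <- rep("", l$channels)
        cpos[[nm]] <- rep(0L, l$channels)
      },
      focus = {
        keeps[[nm]] <- rep(keeps[[l$inputs]], 4L)
        cvals[[nm]] <- rep(cvals[[l$inputs]], 4L)
        cdyn[[nm]] <- rep(cdyn[[l$inputs]], 4L)
        cpos[[nm]] <- rep(cpos[[l$inputs]], 4L)
      },
      conv = {
        kin <- keeps[[l$inputs]]
        kout <- !(g %in% rmset)
        w0 <- l$w
        nl <- l
        b_new <- if (isTRUE(l$bias)) l$b[kout] else NULL
        rm_idx <- which(!kin)
        if (length(rm_idx)) {
          cv <- cvals[[l$inputs]]
          dyn <- cdyn[[l$inputs]]
          stat <- rm_idx[dyn[rm_idx] == ""]
          dynix <- rm_idx[dyn[rm_idx] != ""]
          v <- cv[stat]
          v[is.na(v)] <- 0
          if (length(stat) && any(v != 0)) {
            if (l$k == 1L) {
              ws <- matrix(w0[1, 1, stat, kout], length(stat))
              shift <- as.vector(crossprod(ws, v))
              if (isTRUE(l$bias)) {
                b_new <- b_new + shift
              } else {
                pending[[nm]] <- shift
              }
            } else {
              nl$fold$static <- list(v = v,
                                     w = w0[, , stat, kout, drop = FALSE])
            }
          }
          if (length(dynix)) {
            src <- unique(dyn[dynix])
            if (length(src) == 1L && l$k == 1L) {
              nl$fold$dynamic <- list(
                eca = src, pos = cpos[[l$inputs]][dynix],
                v = cv[dynix],
                S = matrix(w0[1, 1, dynix, kout], length(dynix)))
            } else {
              # fall back to a static fold with unit gate
              v2 <- cv[dynix]
              v2[is.na(v2)] <- 0
              old <- nl$fold$static
              wextra <- w0[, , dynix, kout, drop = FALSE]
              nl$fold$static <- if (is.null(old)) {
                list(v = v2, w = wextra)
              } else {
                list(v = c(old$v, v2), w = abind_c3(old$w, wextra))
              }
            }
          }
        }
        nl$w <- w0[, , kin, kout, drop = FALSE]
        nl$b <- b_new
        nl$cin <- sum(kin)
        nl$cout <- sum(kout)
        out$layers[[nm]] <- nl
        keeps[[nm]] <- kout
        cvals[[nm]] <- ifelse(kout, NA_real_, 0)
        cdyn[[nm]] <- rep("", length(kout))
        cpos[[nm]] <- rep(0L, length(kout))
      },
      bn = {
        kin <- keeps[[l$inputs]]
        nl <- l
        nl$gamma <- l$gamma[kin]
        nl$beta <- l$beta[kin]
        nl$rmean <- l$rmean[kin]
        nl$rvar <- l$rvar[kin]
        sh <- pending[[l$inputs]]
        if (!is.null(sh)) nl$rmean <- nl$rmean - sh
        nl$c <- sum(kin)
        out$layers[[nm]] <- nl
        keeps[[nm]] <- kin
        cvals[[nm]] <- ifelse(kin, NA_real_, l$beta)
        cdyn[[nm]] <- rep("", length(kin))
        cpos[[nm]] <- rep(0L, length(kin))
      },
      act = {
        keeps[[nm]] <- keeps[[l$inputs]]
        cvals[[nm]] <- ifelse(is.na(cvals[[l$inputs]]), NA_real_,
                              act_fwd(l$fun, cvals[[l$inputs]]))
        cdyn[[nm]] <- cdyn[[l$inputs]]
        cpos[[nm]] <- cpos[[l$inputs]]
      },
      dwconv = {
        kin <- keeps[[l$inputs]]
        nl <- l
        nl$w <- l$w[, , kin, drop = FALSE]
        nl$c <- sum(kin)
        out$layers[[nm]] <- nl
        keeps[[nm]] <- kin
        ksum <- apply(l$w, 3, sum)
        cvals[[nm]] <- ifelse(is.na(cvals[[l$inputs]]), NA_real_,
                              cvals[[l$inputs]] * ksum)
        cdyn[[nm]] <- cdyn[[l$inputs]]
        cpos[[nm]] <- cpos[[l$inputs]]
      },
      maxpool = {
        keeps[[nm]] <- keeps[[l$inputs]]
        cvals[[nm]] <- cvals[[l$inputs]]
        cdyn[[nm]] <- cdyn[[l$inputs]]
        cpos[[nm]] <- cpos[[l$inputs]]
      },
      upsample = {
        keeps[[nm]] <- keeps[[l$inputs]]
        cvals[[nm]] <- cvals[[l$inputs]]
        cdyn[[nm]] <- cdyn[[l$inputs]]
        cpos[[nm]] <- cpos[[l$inputs]]
      },
      concat = {
        keeps[[nm]] <- unlist(lapply(l$inputs, function(x) keeps[[x]]))
        cvals[[nm]] <- unlist(lapply(l$inputs, function(x) cvals[[x]]))
        cdyn[[nm]] <- unlist(lapply(l$inputs, function(x) cdyn[[x]]))
        cpos[[nm]] <- unlist(lapply(l$inputs, function(x) cpos[[x]]))
      },
      add = {
        k1 <- keeps[[l$inputs[1]]]
        keeps[[nm]] <- k1
        c1 <- cvals[[l$inputs[1]]]
        c2 <- cvals[[l$inputs[2]]]
        cvals[[nm]] <- ifelse(k1, NA_real_,
                              ifelse(is.na(c1), 0, c1) +
                                ifelse(is.na(c2), 0, c2))
        d1 <- cdyn[[l$inputs[1]]]
        d2 <- cdyn[[l$inputs[2]]]
        cdyn[[nm]] <- ifelse(d1 != "", d1, d2)
        p1 <- cpos[[l$inputs[1]]]
        p2 <- cpos[[l$inputs[2]]]
        cpos[[nm]] <- ifelse(p1 != 0L, p1, p2)
      },
      eca = {
        kin <- keeps[[l$inputs]]
        nl <- l
        rm_pos <- which(!kin)
        if (length(rm_pos)) {
          cst <- cvals[[l$inputs]][rm_pos]
          cst[is.na(cst)] <- 0
          nl$removed <- list(pos = rm_pos, const = cst)
          nl$kept_pos <- which(kin)
          nl$c_orig <- length(kin)
        }
        out$layers[[nm]] <- nl
        keeps[[nm]] <- kin
        cvals[[nm]] <- cvals[[l$inputs]]
        cdyn[[nm]] <- ifelse(kin, "", nm)
        cpos[[nm]] <- ifelse(kin, 0L, match(seq_along(kin), rm_pos))
        cpos[[nm]][is.na(cpos[[nm]])] <- 0L
      },
      asff = {
        k1 <- keeps[[l$inputs[1]]]
        keeps[[nm]] <- k1
        cs <- vapply(l$inputs[1:3], function(x) {
          v <- cvals[[x]]
          ifelse(is.na(v), 0, v)
        }, numeric(length(k1)))
        cvals[[nm]] <- ifelse(k1, NA_real_, rowMeans(matrix(cs, ncol = 3)))
        cdyn[[nm]] <- rep("", length(k1))
        cpos[[nm]] <- rep(0L, length(k1))
      },
      stop("apply_pruning: unknown layer type ", l$type)
    )
  }
  out$pruned_removed <- net$pruned_removed + plan$removed
  out$prunable_total <- plan$prunable_total
  out
}

abind_c3 <- function(a, b) {
  d <- dim(a)
  db <- dim(b)
  y <- array(0, c(d[1], d[2], d[3] + db[3], d[4]))
  y[, , seq_len(d[3]), ] <- a
  y[, , d[3] + seq_len(db[3]), ] <- b
  y
}
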