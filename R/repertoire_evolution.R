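# Ancestral presence/absence reconstruction of gene-family characters on a
# rooted species tree: Fitch small parsimony, Dollo parsimony (single gain,
# any number of losses), and enumeration of alternative gain/loss scenarios
# ranked under a configurable gain penalty. Verbal evolutionary scenarios
# ("retained and repeatedly lost" vs "lost and regained") become points in
# (n_gains, n_losses) space.
#
# Convention: fitch_min_changes leaves the root state free (an all-present
# character costs zero changes); dollo_reconstruction and enumerate_scenarios
# assume the character is absent below the root, so presence at the root
# costs one gain on the root branch.

prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("need an ape 'phylo' tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}

node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) tree$tip.label[node] else paste0("node", node)
}

children_of <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

#' Match tip states to a tree
#'
#' @param tree rooted `phylo` tree.
#' @param tip_states named 0/1 vector; names matched case-insensitively
#'   against tip labels, every tip must receive a state.
#' @return integer vector ordered as `tree$tip.label`.
#' @export
align_tip_states <- function(tree, tip_states) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(tree$tip.label)) {
      stop("unnamed tip states must match the number of tips")
    }
    return(setNames(as.integer(tip_states), tree$tip.label))
  }
  idx <- match(tolower(tree$tip.label), tolower(names(tip_states)))
  if (anyNA(idx)) {
    stop("tip(s) without a state: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  setNames(as.integer(tip_states[idx]), tree$tip.label)
}

#' Extract one character's tip states from a presence matrix
#'
#' @param m [presence_matrix()].
#' @param character column name (e.g. `"type2_cystatin"`).
#' @return named 0/1 vector by lineage.
#' @export
tip_states_from_matrix <- function(m, character) {
  if (!character %in% colnames(m)) {
    stop("character '", character, "' not in matrix")
  }
  setNames(as.integer(m[, character]), rownames(m))
}

#' Fitch small parsimony
#'
#' Standard two-pass Fitch algorithm for a binary character on a rooted tree
#' (polytomies are resolved deterministically first); the root state is free.
#'
#' @param tree rooted `phylo`.
#' @param tip_states named 0/1 vector (see [align_tip_states()]).
#' @return list with `min_changes` and `node_states` (one optimal labeling,
#'   named by tip label / `node<k>`).
#' @export
fitch_min_changes <- function(tree, tip_states) {
  tree <- prepare_tree(tree)
  states <- align_tip_states(tree, tip_states)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- bitwShiftL(1L, states)
  changes <- 0L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    # process each internal node once, when its last child edge appears
    parent <- edges[k, 1L]
    if (sets[parent] != 0L) next
    kids <- children_of(tree, parent)
    if (any(sets[kids] == 0L)) next  # not all children ready yet
    inter <- Reduce(bitwAnd, sets[kids])
    if (inter != 0L) {
      sets[parent] <- inter
    } else {
      sets[parent] <- Reduce(bitwOr, sets[kids])
      changes <- changes + 1L
    }
  }
  # top-down pass
  root <- n_tip + 1L
  node_states <- integer(n_node)
  pick <- function(set, preferred) {
    if (bitwAnd(set, bitwShiftL(1L, preferred)) != 0L) preferred
    else if (bitwAnd(set, 1L) != 0L) 0L else 1L
  }
  node_states[root] <- pick(sets[root], 0L)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    node_states[ch] <- pick(sets[ch], node_states[p])
  }
  names(node_states) <- vapply(seq_len(n_node), node_label, character(1L),
                               tree = tree)
  list(min_changes = changes, node_states = node_states, tree = tree)
}

new_scenario <- function(character, model, node_states, events, k = 1) {
  n_gains <- sum(events$type == "gain")
  n_losses <- sum(events$type == "loss")
  structure(
    list(character = character, model = model, node_states = node_states,
         events = events, n_gains = n_gains, n_losses = n_losses,
         cost = if (startsWith(model, "gain_penalty")) {
           k * n_gains + n_losses
         } else {
           n_gains + n_losses
         }),
    class = "scenario_reconstruction"
  )
}

#' @export
print.scenario_reconstruction <- function(x, ...) {
  cat(sprintf("<%s scenario for '%s': %d gain(s), %d loss(es), cost %g>\n",
              x$model, x$character, x$n_gains, x$n_losses, x$cost))
  if (nrow(x$events)) {
    cat(paste0("  ", x$events$type, " on ", x$events$branch, "\n"), sep = "")
  }
  invisible(x)
}

# TRUE for nodes whose descendant tips are all in state 0
all_zero_below <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  zero <- logical(n_node)
  zero[seq_len(n_tip)] <- states == 0L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]
    kids <- children_of(tree, p)
    zero[p] <- all(zero[kids])
  }
  zero
}

#' Dollo parsimony reconstruction
#'
#' A single gain is placed on the branch above the most recent common
#' ancestor of all tips carrying the character; losses are placed on the
#' branches leading to the maximal all-absent clades inside it. With no
#' presence at all, a degenerate no-gain result is returned.
#'
#' @param tree rooted `phylo`.
#' @param tip_states named 0/1 vector.
#' @param character character name carried in the result.
#' @return `scenario_reconstruction` with `model = "dollo"` (`n_gains <= 1`).
#' @export
dollo_reconstruction <- function(tree, tip_states, character = "character") {
  tree <- prepare_tree(tree)
  states <- align_tip_states(tree, tip_states)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_states <- setNames(integer(n_node),
                          vapply(seq_len(n_node), node_label, character(1L),
                                 tree = tree))
  ones <- which(states == 1L)
  events <- data.frame(branch = character(0), type = character(0),
                       stringsAsFactors = FALSE)
  if (!length(ones)) {
    return(new_scenario(character, "dollo", node_states, events))
  }
  root <- n_tip + 1L
  m <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)
  gain_branch <- if (m == root) "root" else node_label(tree, m)
  events <- rbind(events, data.frame(branch = gain_branch, type = "gain",
                                     stringsAsFactors = FALSE))
  zero <- all_zero_below(tree, states)
  # preorder from m: present unless an all-absent clade starts
  node_states[m] <- 1L
  queue <- m
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in children_of(tree, v)) {
      if (zero[ch]) {
        events <- rbind(events,
                        data.frame(branch = node_label(tree, ch),
                                   type = "loss", stringsAsFactors = FALSE))
        # clade stays 0
      } else {
        node_states[ch] <- 1L
        if (ch > n_tip) queue <- c(queue, ch)
      }
    }
  }
  out <- new_scenario(character, "dollo", node_states, events)
  out$tree <- tree
  out
}

#' Enumerate alternative gain/loss scenarios
#'
#' For every achievable gain count `g <= max_gains` the reconstruction with
#' the fewest losses is computed exactly (dynamic programming over the tree,
#' character assumed absent below the root), and the scenarios are ranked by
#' `cost = gain_penalty * n_gains + n_losses`, ties broken by fewer total
#' events, then by smaller gain count.
#'
#' @param tree rooted `phylo`.
#' @param tip_states named 0/1 vector.
#' @param max_gains maximum number of gains considered (>= 1).
#' @param gain_penalty cost multiplier `k` for a gain (default 2; gains are
#'   rarer events than losses).
#' @param character character name carried in the results.
#' @return list of `scenario_reconstruction`, ranked; with `max_gains = 1`
#'   this is exactly the Dollo solution.
#' @export
enumerate_scenarios <- function(tree, tip_states, max_gains = 3L,
                                gain_penalty = 2, character = "character") {
  if (max_gains < 1L) stop("max_gains must be >= 1")
  tree <- prepare_tree(tree)
  states <- align_tip_states(tree, tip_states)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  G <- as.integer(max_gains)
  INF <- Inf

  # L[[node]][s + 1, g + 1] = min losses in the subtree of `node` given the
  # node is in state s with exactly g gains on edges strictly below it
  L <- vector("list", n_node)
  for (tip in seq_len(n_tip)) {
    m <- matrix(INF, 2L, G + 1L)
    m[states[tip] + 1L, 1L] <- 0
    L[[tip]] <- m
  }
  edge_cost <- function(s_par, s_child) {
    c(gain = as.integer(s_par == 0L && s_child == 1L),
      loss = as.integer(s_par == 1L && s_child == 0L))
  }
  # min losses contributed by child `ch` seen from a parent in state s,
  # using exactly g gains on the connecting edge plus the child's subtree
  child_table <- function(ch) {
    m <- matrix(INF, 2L, G + 1L)
    for (s_par in 0:1) {
      for (s_ch in 0:1) {
        ec <- edge_cost(s_par, s_ch)
        for (g in 0:G) {
          gg <- g - ec[["gain"]]
          if (gg < 0L) next
          v <- L[[ch]][s_ch + 1L, gg + 1L] + ec[["loss"]]
          if (v < m[s_par + 1L, g + 1L]) m[s_par + 1L, g + 1L] <- v
        }
      }
    }
    m
  }
  minplus <- function(a, b) {
    out <- rep(INF, G + 1L)
    for (g in 0:G) {
      for (g1 in 0:g) {
        v <- a[g1 + 1L] + b[g - g1 + 1L]
        if (v < out[g + 1L]) out[g + 1L] <- v
      }
    }
    out
  }
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]
    if (done[p]) next
    kids <- children_of(tree, p)
    if (!all(done[kids])) next
    m <- matrix(INF, 2L, G + 1L)
    for (s in 0:1) {
      acc <- c(0, rep(INF, G))
      for (ch in kids) acc <- minplus(acc, child_table(ch)[s + 1L, ])
      m[s + 1L, ] <- acc
    }
    L[[p]] <- m
    done[p] <- TRUE
  }

  # totals with the virtual pre-root ancestor in state 0
  total <- rep(INF, G + 1L)
  root_state_for <- rep(NA_integer_, G + 1L)
  for (g in 0:G) {
    for (s_r in 0:1) {
      gg <- g - as.integer(s_r == 1L)
      if (gg < 0L) next
      v <- L[[root]][s_r + 1L, gg + 1L]
      if (v < total[g + 1L]) {
        total[g + 1L] <- v
        root_state_for[g + 1L] <- s_r
      }
    }
  }

  # traceback one optimal labeling for a given total gain count
  reconstruct <- function(g_total) {
    node_states <- setNames(integer(n_node),
                            vapply(seq_len(n_node), node_label,
                                   character(1L), tree = tree))
    assign_down <- function(v, s, g) {
      node_states[node_label(tree, v)] <<- s
      if (v <= n_tip) return(invisible(NULL))
      kids <- children_of(tree, v)
      tabs <- lapply(kids, child_table)
      # find a split of g across children consistent with the DP value
      target <- L[[v]][s + 1L, g + 1L]
      if (length(kids) == 1L) {
        splits <- matrix(g, 1L, 1L)
      } else {
        splits <- cbind(0:g, g - (0:g))
      }
      for (r in seq_len(nrow(splits))) {
        ok <- sum(vapply(seq_along(kids), function(i) {
          tabs[[i]][s + 1L, splits[r, i] + 1L]
        }, numeric(1L)))
        if (is.finite(ok) && ok == target) {
          for (i in seq_along(kids)) {
            gi <- splits[r, i]
            # pick the child state realizing tabs[[i]][s+1, gi+1]
            for (s_ch in c(s, 1L - s)) {
              ec <- edge_cost(s, s_ch)
              gg <- gi - ec[["gain"]]
              if (gg >= 0L &&
                  L[[kids[i]]][s_ch + 1L, gg + 1L] + ec[["loss"]] ==
                  tabs[[i]][s + 1L, gi + 1L]) {
                assign_down(kids[i], s_ch, gg)
                break
              }
            }
          }
          return(invisible(NULL))
        }
      }
      stop("internal error: traceback failed")
    }
    s_r <- root_state_for[g_total + 1L]
    assign_down(root, s_r, g_total - as.integer(s_r == 1L))
    node_states
  }

  events_from_states <- function(node_states) {
    ev <- list()
    if (node_states[[node_label(tree, root)]] == 1L) {
      ev[[length(ev) + 1L]] <- data.frame(branch = "root", type = "gain",
                                          stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      sp <- node_states[[node_label(tree, p)]]
      sc <- node_states[[node_label(tree, ch)]]
      if (sp != sc) {
        ev[[length(ev) + 1L]] <- data.frame(
          branch = node_label(tree, ch),
          type = if (sc == 1L) "gain" else "loss",
          stringsAsFactors = FALSE)
      }
    }
    if (!length(ev)) {
      return(data.frame(branch = character(0), type = character(0),
                        stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, ev)
    df[order(df$type, df$branch), , drop = FALSE]
  }

  scenarios <- list()
  for (g in 0:G) {
    if (!is.finite(total[g + 1L])) next
    if (g == 0L && any(states == 1L)) next
    ns <- reconstruct(g)
    ev <- events_from_states(ns)
    sc <- new_scenario(character, sprintf("gain_penalty(%g)", gain_penalty),
                       ns, ev, k = gain_penalty)
    sc$tree <- tree
    scenarios[[length(scenarios) + 1L]] <- sc
  }
  ord <- order(vapply(scenarios, `[[`, numeric(1L), "cost"),
               vapply(scenarios, function(x) x$n_gains + x$n_losses,
                      numeric(1L)),
               vapply(scenarios, `[[`, numeric(1L), "n_gains"))
  scenarios[ord]
}

#' Tabulate scenarios
#'
#' @param scenarios list from [enumerate_scenarios()].
#' @return data.frame `rank`, `model`, `n_gains`, `n_losses`, `cost`,
#'   `gain_branches`, `loss_branches`.
#' @export
scenario_table <- function(scenarios) {
  data.frame(
    rank = seq_along(scenarios),
    model = vapply(scenarios, `[[`, character(1L), "model"),
    n_gains = vapply(scenarios, `[[`, numeric(1L), "n_gains"),
    n_losses = vapply(scenarios, `[[`, numeric(1L), "n_losses"),
    cost = vapply(scenarios, `[[`, numeric(1L), "cost"),
    gain_branches = vapply(scenarios, function(x) {
      paste(x$events$branch[x$events$type == "gain"], collapse = ";")
    }, character(1L)),
    loss_branches = vapply(scenarios, function(x) {
      paste(x$events$branch[x$events$type == "loss"], collapse = ";")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
}
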