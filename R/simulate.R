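# Simulators: pure-birth (Yule) trees with heterogeneous branch lengths, and
# binary per-leaf outcomes with controlled phylogenetic structure. The clade
# model couples the positive-outcome clade to the focal leaf, emulating a
# screen where complementation concentrates near the host ortholog; the
# random model emulates a screen with no phylogenetic structure.

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from two lineages at the root, waiting times
#' between speciation events are exponential with rate k * birth_rate while k
#' lineages are extant, and a uniformly chosen lineage splits at each event.
#' A final exponential interval at n lineages is appended, so the expected
#' root-to-tip depth is sum_{k=2..n} 1/(k * birth_rate). Deterministic given
#' `seed`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Speciation rate (> 0), events per unit branch length.
#' @param seed Integer seed; recorded in the tree's `"sim_params"` attribute.
#' @return A `phylo` tree with leaves `t1..tn` and positive branch lengths.
#' @export
#' @examples
#' tr <- simulate_yule_tree(8, seed = 1)
simulate_yule_tree <- function(n_leaves, birth_rate = 1, seed = 1L) {
  if (!is.numeric(n_leaves) || n_leaves < 2L) {
    stop("`n_leaves` must be at least 2", call. = FALSE)
  }
  if (birth_rate <= 0) stop("`birth_rate` must be positive", call. = FALSE)
  n_leaves <- as.integer(n_leaves)
  tree <- withr::with_seed(seed, yule_grow(n_leaves, birth_rate))
  attr(tree, "sim_params") <- list(n_leaves = n_leaves, birth_rate = birth_rate,
                                   seed = seed)
  tree
}

yule_grow <- function(n, rate) {
  # parent/length arrays over nodes; node 1 = root, lineages are growing tips
  parent <- c(NA_integer_, 1L, 1L)
  len <- c(0, 0, 0)
  active <- c(2L, 3L)
  k <- 2L
  while (k < n) {
    len[active] <- len[active] + stats::rexp(1L, rate = k * rate)
    split_i <- active[sample.int(k, 1L)]
    id1 <- length(parent) + 1L
    id2 <- length(parent) + 2L
    parent <- c(parent, split_i, split_i)
    len <- c(len, 0, 0)
    active <- c(setdiff(active, split_i), id1, id2)
    k <- k + 1L
  }
  len[active] <- len[active] + stats::rexp(1L, rate = n * rate)
  kids <- split(seq_along(parent)[-1L], parent[-1L])
  tip_counter <- 0L
  as_newick <- function(node) {
    ch <- kids[[as.character(node)]]
    if (is.null(ch)) {
      tip_counter <<- tip_counter + 1L
      return(sprintf("t%d:%.12g", tip_counter, len[node]))
    }
    inner <- paste(vapply(ch, as_newick, character(1)), collapse = ",")
    sprintf("(%s):%.12g", inner, len[node])
  }
  txt <- paste0("(", paste(vapply(kids[["1"]], as_newick, character(1)),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

#' Simulate a binary outcome on a tree
#'
#' Three generating models for per-leaf `+`/`-` outcomes:
#'
#' * `"clade_gain"`: the internal node containing `focal` whose leaf count is
#'   closest to `clade_fraction * n` defines a signal clade; leaves inside are
#'   positive with probability `p_in`, outside with `p_out`. Because the
#'   clade contains the focal leaf, clade membership and patristic distance
#'   from the focal are coupled (the high-eta regime).
#' * `"distance_decay"`: P(+) = 1 / (1 + exp((d - d0) / s)) with d the
#'   patristic distance from `focal`.
#' * `"random"`: iid Bernoulli(`base`), no phylogenetic structure
#'   (the eta-near-zero regime).
#'
#' Deterministic given `seed`.
#'
#' @param tree A `phylo` tree.
#' @param focal Focal leaf label (default: first tip).
#' @param model `"clade_gain"`, `"distance_decay"`, or `"random"`.
#' @param p_in,p_out Positive-outcome probabilities inside/outside the signal
#'   clade (clade model).
#' @param clade_fraction Target clade size as a fraction of n, in (0, 1).
#' @param d0,s Distance midpoint and decay scale (distance model), branch
#'   length units; `s > 0`.
#' @param base Positive rate (random model).
#' @param seed Integer seed.
#' @return A `sim_screen`: list with `tree`, `focal`, `outcomes` (tibble
#'   `leaf`, `outcome`) and `params` (including the realized signal clade for
#'   the clade model).
#' @export
simulate_trait <- function(tree, focal = NULL,
                           model = c("clade_gain", "distance_decay", "random"),
                           p_in = 0.95, p_out = 0.05, clade_fraction = 0.5,
                           d0 = 1, s = 0.25, base = 0.3, seed = 1L) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  labs <- tree$tip.label
  if (is.null(focal)) focal <- labs[1L]
  if (!focal %in% labs) stop("focal leaf '", focal, "' not in tree", call. = FALSE)
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            clade_fraction > 0, clade_fraction < 1, s > 0,
            base >= 0, base <= 1)
  n <- length(labs)
  params <- list(model = model, seed = seed, focal = focal)
  prob <- switch(model,
    clade_gain = {
      members <- focal_clade(tree, focal, clade_fraction)
      params$clade_leaves <- members
      params$p_in <- p_in; params$p_out <- p_out
      params$clade_fraction <- clade_fraction
      ifelse(labs %in% members, p_in, p_out)
    },
    distance_decay = {
      df <- distances_from(tree, focal)
      d <- stats::setNames(numeric(n), labs)
      d[df$leaf] <- df$distance
      params$d0 <- d0; params$s <- s
      unname(1 / (1 + exp((d[labs] - d0) / s)))
    },
    random = {
      params$base <- base
      rep(base, n)
    }
  )
  draws <- withr::with_seed(seed, stats::runif(n))
  outcomes <- tibble::tibble(
    leaf = labs,
    outcome = ifelse(draws < prob, "+", "-")
  )
  structure(list(tree = tree, focal = focal, outcomes = outcomes,
                 params = params),
            class = "sim_screen")
}

# Internal node (possibly the root) containing `focal` whose descendant leaf
# count is closest to clade_fraction * n; ties go to the smaller clade.
focal_clade <- function(tree, focal, clade_fraction) {
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("tree too small for a signal clade", call. = FALSE)
  desc <- tip_descendants(tree)
  focal_i <- match(focal, tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  holds <- internal[vapply(internal, function(nd) focal_i %in% desc[[nd]], logical(1))]
  if (length(holds) == 0L) stop("no internal node contains the focal leaf", call. = FALSE)
  sizes <- vapply(holds, function(nd) length(desc[[nd]]), integer(1))
  target <- clade_fraction * ntip
  best <- holds[order(abs(sizes - target), sizes)][1L]
  tree$tip.label[desc[[best]]]
}

#' @export
print.sim_screen <- function(x, ...) {
  cat("Simulated screen (", x$params$model, " model, seed ", x$params$seed,
      "): ", nrow(x$outcomes), " leaves, ",
      sum(x$outcomes$outcome == "+"), " positive; focal = ", x$focal,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sim_screen <- function(x, ...) x$outcomes

#' Permutation null distribution of eta
#'
#' Recomputes the correlation ratio between outcome and patristic distance
#' from the focal leaf under random permutations of the outcome labels
#' (leaves other than the focal), giving an empirical null for the observed
#' eta. Permutations that leave a single outcome category (possible only for
#' degenerate inputs) are skipped and counted.
#'
#' @param tree A `phylo` tree.
#' @param focal Focal leaf label.
#' @param outcomes A tibble (`leaf`, `outcome`) as produced by
#'   [simulate_trait()], or a named character vector.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @return An `eta_null`: `observed` eta, `null` (numeric vector),
#'   `percentile` of the observed value in the null (fraction of null values
#'   <= observed), `n_skipped`.
#' @export
eta_null_distribution <- function(tree, focal, outcomes, n_permutations = 500,
                                  seed = 1L) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (is.data.frame(outcomes)) {
    oc <- stats::setNames(outcomes$outcome, outcomes$leaf)
  } else {
    oc <- outcomes
  }
  d <- distances_from(tree, focal)
  labels <- unname(oc[d$leaf])
  if (anyNA(labels)) stop("outcomes missing for some leaves", call. = FALSE)
  observed <- correlation_ratio(labels, d$distance)$eta
  skipped <- 0L
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- sample(labels)
      if (length(unique(perm)) < 2L) {
        skipped <<- skipped + 1L
        return(NA_real_)
      }
      correlation_ratio(perm, d$distance)$eta
    }, numeric(1))
  })
  null <- null[!is.na(null)]
  structure(
    list(observed = observed, null = null,
         percentile = mean(null <= observed),
         n_permutations = n_permutations, n_skipped = skipped,
         seed = seed, focal = focal),
    class = "eta_null"
  )
}

#' @export
print.eta_null <- function(x, ...) {
  cat("Permutation null for eta (", length(x$null), " permutations)\n",
      "  observed eta = ", signif(x$observed, 4),
      ", empirical percentile = ", signif(x$percentile, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.eta_null <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, percentile = x$percentile,
    null_mean = mean(x$null), null_q95 = unname(stats::quantile(x$null, 0.95)),
    n_permutations = x$n_permutations, n_skipped = x$n_skipped
  )
}

#' Write a simulated screen to disk
#'
#' Writes the tree as Newick and the outcomes (with generating parameters as
#' a JSON sidecar) as TSV in the screen join-key format.
#'
#' @param sim A `sim_screen`.
#' @param out_prefix Path prefix; files `<prefix>.nwk`, `<prefix>_outcomes.tsv`
#'   and `<prefix>_params.json` are written.
#' @return `out_prefix`, invisibly.
#' @export
write_sim_screen <- function(sim, out_prefix) {
  write_newick(sim$tree, paste0(out_prefix, ".nwk"))
  readr::write_tsv(sim$outcomes, paste0(out_prefix, "_outcomes.tsv"))
  jsonlite::write_json(sim$params, paste0(out_prefix, "_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_prefix)
}
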