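# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths: brute-force enumeration for parsimony, the
# hypergeometric permutation distribution for the 2x2 test.

# Minimum change count by exhaustive enumeration of all internal labelings.
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  st <- tip_states[tree$tip.label]
  states <- c(ifelse(st == "present", 1L, 0L), rep(NA_integer_, nnode))
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    lab <- states
    lab[(ntip + 1):(ntip + nnode)] <- bitwAnd(bitwShiftR(mask, 0:(nnode - 1)), 1L)
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# Random rooted binary tree with n tips (labels t1..tn), built by
# sequentially attaching tips — independent of ape's simulators.
random_tree <- function(n) {
  stopifnot(n >= 2)
  txt <- "(t1,t2)"
  for (i in seq_len(n - 2) + 2) {
    # pick a random tip already in the tree and split it
    target <- paste0("t", sample(i - 1, 1))
    txt <- sub(paste0("(?<![0-9])", target, "(?![0-9])"),
               paste0("(", target, ",t", i, ")"), txt, perl = TRUE)
  }
  ape::read.tree(text = paste0(txt, ";"))
}

# Exact permutation p-value for a 2x2 table with fixed margins: the
# probability, under the hypergeometric distribution, of a table at least
# as extreme as observed. Extremeness is |a - E[a]|, which is equivalent
# to ordering by the Pearson statistic at fixed margins but computed
# without it.
perm_exact_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  ea <- r1 * c1 / n
  dev_obs <- abs(m[1, 1] - ea)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_range, r1, r2, c1)
  sum(probs[abs(a_range - ea) >= dev_obs - 1e-9])
}

# Tiny presence matrix built by hand.
toy_matrix <- function() {
  inv <- list(
    m1 = c("psbA", "rbcL", "pbsA", "ycf34"),
    m2 = c("psbA", "rbcL", "pbsA", "ycf34"),
    m3 = c("psbA", "rbcL", "pbsA"),
    f1 = c("psbA", "rbcL"),
    f2 = c("psbA", "rbcL", "ycf91")
  )
  hab <- c(m1 = "marine", m2 = "marine", m3 = "marine",
           f1 = "freshwater", f2 = "freshwater")
  build_matrix(inv, hab)
}

# Shared domain profile: building it costs a second or two, do it once.
shared_profile <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) prof <<- hemeo_profile()
    prof
  }
})
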