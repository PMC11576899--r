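## Founder diversity: neutral Kingman coalescent at mutation-drift
## equilibrium, one unlinked interval at a time.  Haplotypes sampled here
## seed the forward Wright-Fisher phase; within-interval recombination is
## handled forward in time, so the founder tree is non-recombining.

## Simulate a Kingman coalescent tree for n leaves.  Times in units of 2N
## generations.  Returns parent pointers and node times; nodes 1..n are
## leaves, internal nodes n+1..2n-1 are created in increasing time order,
## so every child id is smaller than its parent id.
sim_coalescent_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  ntime <- numeric(n_nodes)
  active <- seq_len(n)
  ks <- seq.int(n, 2L)
  ## batched RNG: one exponential waiting time and one lineage pair per
  ## coalescence event
  waits <- stats::rexp(n - 1L, ks * (ks - 1L) / 2)
  u1 <- stats::runif(n - 1L)
  u2 <- stats::runif(n - 1L)
  t <- 0
  k <- n
  for (j in seq_len(n - 1L)) {
    t <- t + waits[j]
    p1 <- 1L + as.integer(u1[j] * k)          # uniform on 1..k
    p2 <- 1L + as.integer(u2[j] * (k - 1L))   # uniform on 1..k-1
    if (p2 >= p1) p2 <- p2 + 1L               # distinct pair
    new_id <- n + j
    parent[active[p1]] <- new_id
    parent[active[p2]] <- new_id
    ntime[new_id] <- t
    ## swap-with-last removal, then overwrite with the new lineage
    active[p1] <- new_id
    active[p2] <- active[k]
    k <- k - 1L
  }
  list(parent = parent, time = ntime, n = n)
}

## Equilibrium founder haplotypes for one interval.
##
## n_leaves: haplotype sample size (2 x founder diploids)
## ne: diploid size of the equilibrium ancestral population
## mu: per-bp per-generation mutation rate; len: interval length (bp)
##
## Returns a list: `mat` raw 0/1 matrix (n_leaves x S, derived allele = 1)
## and `pos` integer site positions (1-based within the interval), sorted.
## Infinite-sites: at most one mutation per bp position.
##
## Carrier extraction uses the standard contiguity trick: leaves are
## re-ordered by a preorder traversal so that every subtree occupies a
## contiguous range [lo, hi] of the leaf ordering; a mutation on the edge
## above node v then flips exactly leaf_order[lo[v]:hi[v]].
sim_founder_interval <- function(n_leaves, ne, mu, len) {
  tree <- sim_coalescent_tree(n_leaves)
  n <- n_leaves
  n_nodes <- 2L * n - 1L
  root <- n_nodes
  ## binary children table (children precede parents in id order)
  kid <- matrix(0L, n - 1L, 2L)
  slot <- integer(n - 1L)
  for (v in seq_len(n_nodes - 1L)) {
    p <- tree$parent[v] - n
    s <- slot[p] + 1L
    slot[p] <- s
    kid[p, s] <- v
  }
  ## preorder DFS with a manual stack: leaf positions
  leaf_order <- integer(n)
  pos_of <- integer(n_nodes)
  stack <- integer(n_nodes)
  sp <- 1L; stack[1L] <- root
  cnt <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    if (v <= n) {
      cnt <- cnt + 1L
      leaf_order[cnt] <- v
      pos_of[v] <- cnt
    } else {
      stack[sp + 1L] <- kid[v - n, 1L]
      stack[sp + 2L] <- kid[v - n, 2L]
      sp <- sp + 2L
    }
  }
  ## contiguous leaf range per node, children before parents
  lo <- integer(n_nodes); hi <- integer(n_nodes)
  lo[seq_len(n)] <- pos_of[seq_len(n)]
  hi[seq_len(n)] <- pos_of[seq_len(n)]
  for (v in (n + 1L):n_nodes) {
    k1 <- kid[v - n, 1L]; k2 <- kid[v - n, 2L]
    lo[v] <- min(lo[k1], lo[k2])
    hi[v] <- max(hi[k1], hi[k2])
  }
  ## mutations: theta/2 per lineage per 2N generations, theta = 4*ne*mu*len
  nodes <- seq_len(n_nodes - 1L)
  elen <- tree$time[tree$parent[nodes]] - tree$time[nodes]
  rate <- 2 * ne * mu * len
  n_mut <- stats::rpois(1L, sum(elen) * rate)
  n_mut <- min(n_mut, len)      # infinite-sites cap: one site per bp
  if (n_mut == 0L)
    return(list(mat = matrix(raw(0), n_leaves, 0L), pos = integer(0)))
  medge <- sample.int(length(nodes), n_mut, replace = TRUE, prob = elen)
  ## positions sorted; pairing with edges is exchangeable, so sorting
  ## positions first leaves the joint distribution unchanged
  pos <- sort(sample.int(len, n_mut))
  mat <- matrix(as.raw(0L), n_leaves, n_mut)
  for (s in seq_len(n_mut)) {
    v <- medge[s]
    mat[leaf_order[lo[v]:hi[v]], s] <- as.raw(1L)
  }
  list(mat = mat, pos = pos)
}
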