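clade <- function(hc, k) {
  stack <- k; out <- integer()
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v < 0) out <- c(out, -v) else stack <- c(stack, hc$merge[v, ])
  }
  out
}

test_that("binary profile distances match their definitions and a naive loop", {
  m <- rbind(g1 = c(1L, 0L, 0L), g2 = c(0L, 1L, 0L))
  colnames(m) <- c("s1", "s2", "s3")
  expect_equal(as.numeric(profile_distances(m, "genes", "euclidean")), sqrt(2))
  expect_equal(as.numeric(profile_distances(m, "genes", "mean_squared")), 2 / 3)

  m2 <- rbind(g1 = c(1L, 1L, 0L), g2 = c(1L, 1L, 0L))
  colnames(m2) <- c("s1", "s2", "s3")
  expect_equal(as.numeric(profile_distances(m2, "genes")), 0)

  set.seed(5)
  for (rep in 1:5) {
    m3 <- random_binary_matrix(6, 10)
    naive <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
      sqrt(sum((m3[i, ] - m3[j, ])^2))))
    expect_equal(as.matrix(profile_distances(m3, "genes")), naive,
                 ignore_attr = TRUE)
    naive_ms <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
      mean((m3[i, ] - m3[j, ])^2)))
    expect_equal(as.matrix(profile_distances(m3, "genes", "mean_squared")),
                 naive_ms, ignore_attr = TRUE)
  }

  expect_error(profile_distances(m[1, , drop = FALSE], "genes"),
               "at least two")
})

test_that("average linkage reproduces hand-worked merges", {
  # d(AB)=1, d(AC)=d(BC)=4: AB at 1, then C joins at 4
  d <- as.dist(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3))
  attr(d, "Labels") <- c("A", "B", "C")
  hc <- average_linkage(d)
  expect_equal(hc$height, c(1, 4))
  expect_equal(sort(hc$labels[clade(hc, 1L)]), c("A", "B"))

  # two identical points among three: first merge at height zero
  m <- rbind(a = c(1L, 0L), b = c(1L, 0L), c = c(0L, 1L))
  colnames(m) <- c("s1", "s2")
  hc0 <- average_linkage(profile_distances(m, "genes"))
  expect_equal(hc0$height[1L], 0)

  dn <- d; dn[1] <- NaN
  expect_error(average_linkage(dn), "NaN|non-finite")
})

test_that("average linkage agrees with stats::hclust on tie-free instances", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    d <- random_dist(n)
    hc <- average_linkage(d)
    ref <- stats::hclust(d, method = "average")
    expect_equal(hc$height, ref$height, tolerance = 1e-12)
    expect_equal(lapply(hclust_members(hc), sort),
                 lapply(hclust_members(ref), sort))
  }
})

test_that("merge heights are monotone nondecreasing", {
  set.seed(23)
  for (rep in 1:10) {
    m <- random_binary_matrix(15, 8)
    hc <- average_linkage(profile_distances(m, "genes"))
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("ciliated-left ordering moves the denser clade first", {
  # ((c,n),(c,c)): the all-ciliated right clade must come left
  m <- rbind(g1 = c(1L, 0L, 1L, 1L), g2 = c(0L, 1L, 1L, 1L),
             g3 = c(1L, 1L, 0L, 0L))
  colnames(m) <- c("c1", "n1", "c2", "c3")
  shc <- average_linkage(profile_distances(m, "species"))
  ann <- make_annotations(colnames(m), c(TRUE, FALSE, TRUE, TRUE))
  ord <- order_leaves_ciliated_left(shc, ann)
  expect_setequal(as.character(ord), colnames(m))
  expect_true(which(ord == "n1") == 4L)  # the only non-ciliated leaf is last

  # all ciliated: ordering ties everywhere, input order preserved
  ann_all <- make_annotations(colnames(m), rep(TRUE, 4))
  ord_all <- order_leaves_ciliated_left(shc, ann_all)
  expect_equal(as.character(ord_all), shc$labels[shc$order])

  expect_error(order_leaves_ciliated_left(shc, ann[-1, ]), "unannotated")
})

test_that("ciliated-left ordering is optimal on exhaustively checked trees", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    d <- random_dist(n)
    hc <- average_linkage(d)
    ciliated <- runif(n) < 0.5
    ann <- make_annotations(attr(d, "Labels"), ciliated)
    ord <- order_leaves_ciliated_left(hc, ann)
    expect_equal(attr(ord, "objective"), ciliated_left_oracle(hc, ciliated))
    # and never worse than the raw dendrogram order
    raw <- sum(seq_len(n)[ciliated[hc$order]])
    expect_lte(attr(ord, "objective"), raw)
  }
})

test_that("seed cluster extraction recovers a planted co-lost module", {
  sim <- simulate_ciliome(tiny_sim_config(101))
  hc <- average_linkage(profile_distances(sim$matrix, "genes"))
  cl <- extract_seed_cluster(hc, sim$truth$seed_gene, "elbow")
  expect_setequal(cl$members, names(sim$truth$modules))

  # growth trace is nondecreasing in both height and size
  expect_true(all(diff(cl$growth_trace$height) >= -1e-12))
  expect_true(all(diff(cl$growth_trace$size) > 0))

  # a cut below the first merge leaves the seed alone
  solo <- extract_seed_cluster(hc, sim$truth$seed_gene, "fixed_height",
                               param = -1)
  expect_equal(solo$members, sim$truth$seed_gene)

  # target_size returns the smallest seed clade of at least that size
  k <- length(sim$truth$modules)
  cl_k <- extract_seed_cluster(hc, sim$truth$seed_gene, "target_size",
                               param = k)
  expect_gte(length(cl_k$members), k)
  trace <- cl_k$growth_trace
  smaller <- trace$size[trace$size < length(cl_k$members)]
  expect_true(all(smaller < k))

  expect_error(extract_seed_cluster(hc, "nope", "elbow"), "not found")
})

test_that("stratified subsampling keeps the planted cluster at zero noise", {
  sim <- simulate_ciliome(tiny_sim_config(55))
  ref_hc <- average_linkage(profile_distances(sim$matrix, "genes"))
  ref <- extract_seed_cluster(ref_hc, sim$truth$seed_gene, "elbow")

  # removing nothing is the identity
  r0 <- robustness_subsample(sim$matrix, sim$annotations, sim$truth$seed_gene,
                             fraction = 0, rng_seed = 1, reference = ref)
  expect_equal(r0$retained_count, length(ref$members))

  r50 <- robustness_subsample(sim$matrix, sim$annotations, sim$truth$seed_gene,
                              fraction = 0.5, rng_seed = 1, reference = ref)
  expect_equal(r50$retained_count, length(sim$truth$modules))
  # stratification: half of each group removed
  grp <- table(sim$annotations$major_group[
    match(r50$species_used, sim$annotations$species_id)])
  expect_true(all(grp == c(alveolata = 4, opisthokonta = 4,
                           prokaryote = 1, stramenopila = 4)[names(grp)]))

  # wiping out a whole group is refused
  tiny <- sim$annotations
  tiny$major_group[tiny$species_id == colnames(sim$matrix)[1]] <- "rhizaria"
  expect_error(
    robustness_subsample(sim$matrix, tiny, sim$truth$seed_gene,
                         fraction = 0.6, rng_seed = 1, reference = ref),
    "entire major group")
})
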