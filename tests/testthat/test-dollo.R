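test_that("Dollo loss counting matches hand-worked cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all_present <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(count_independent_losses(tr, all_present)$total_losses, 0L)

  # B lost alone, and the whole CD clade lost: two events
  rep2 <- count_independent_losses(tr, c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(rep2$total_losses, 2L)
  tipsets <- lapply(rep2$loss_edges, function(e) sort(e$tips))
  expect_setequal(tipsets, list("B", c("C", "D")))

  expect_error(count_independent_losses(tr, c(A = 1, B = 0, C = 0)),
               "trait missing")
})

test_that("Dollo count is invariant to child rotation and safe refinement", {
  trait <- c(A = 1, B = 0, C = 0, D = 1, E = 0)
  t1 <- ape::read.tree(text = "((A,(B,C)),(D,E));")
  t2 <- ape::read.tree(text = "((E,D),((C,B),A));")     # rotated
  expect_equal(count_independent_losses(t1, trait)$total_losses,
               count_independent_losses(t2, trait)$total_losses)

  # polytomy vs a refinement that keeps the absent leaves together
  p1 <- ape::read.tree(text = "(A,B,C,D);")
  p2 <- ape::read.tree(text = "((A,D),(B,C));")
  tr2 <- c(A = 1, B = 0, C = 0, D = 1)
  expect_equal(count_independent_losses(p1, tr2)$total_losses, 2L)
  expect_equal(count_independent_losses(p2, tr2)$total_losses, 1L)
})

test_that("losses are attributed to major groups", {
  tr <- ape::read.tree(text = "(((o1,o2),o3),((a1,a2),a3));")
  groups <- c(o1 = "opisthokonta", o2 = "opisthokonta", o3 = "opisthokonta",
              a1 = "alveolata", a2 = "alveolata", a3 = "alveolata")
  trait <- c(o1 = 0, o2 = 0, o3 = 1, a1 = 1, a2 = 1, a3 = 0)
  rep <- count_independent_losses(tr, trait, groups)
  expect_equal(rep$total_losses, 2L)
  expect_equal(rep$per_group_losses[["opisthokonta"]], 1L)
  expect_equal(rep$per_group_losses[["alveolata"]], 1L)
})

test_that("loss patterns discretise category fractions with 2/3-1/3 bounds", {
  # 3 species x 2 categories engineered to hit 1.0 / 0.5 / 0.2
  genes <- sprintf("g%02d", 1:20)
  cats <- setNames(rep(c("catA", "catB"), each = 10), genes)
  m <- matrix(0L, 20, 3, dimnames = list(genes, c("s1", "s2", "s3")))
  m[, "s1"] <- 1L                              # fraction 1.0 in both
  m[1:5, "s2"] <- 1L; m[11:15, "s2"] <- 1L     # 0.5
  m[1:2, "s3"] <- 1L; m[11:12, "s3"] <- 1L     # 0.2
  pat <- classify_loss_patterns(m, cats)
  expect_equal(unname(pat$states["s1", ]), c("high", "high"))
  expect_equal(unname(pat$states["s2", ]), c("mid", "mid"))
  expect_equal(unname(pat$states["s3", ]), c("low", "low"))
  expect_equal(pat$n_patterns, 3L)

  # boundary points land in mid on both sides
  m2 <- matrix(0L, 3, 2, dimnames = list(c("x1", "x2", "x3"), c("t1", "t2")))
  m2[1:2, "t1"] <- 1L   # 2/3
  m2[1, "t2"] <- 1L     # 1/3
  pat2 <- classify_loss_patterns(m2, setNames(rep("c", 3), rownames(m2)))
  expect_equal(unname(pat2$states[, "c"]), c("mid", "mid"))

  # pattern count can never exceed the combinatorial or species bound
  expect_lte(pat$n_patterns, min(3^2, 3))
  expect_error(classify_loss_patterns(m, setNames(character(), character())),
               "no categorised genes")
})

test_that("footprint prediction follows the conservation decision rule", {
  sp <- sprintf("s%02d", 1:12)
  # 8 motile-ciliated, 2 nonmotile-ciliated (nematode/tick class), 2 nonciliated
  ann <- make_annotations(sp, c(rep(TRUE, 10), FALSE, FALSE),
                          motile = c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE))
  row_named <- function(v) setNames(as.integer(v), sp)

  # present in 4/10 ciliated species: below the 50% floor
  low <- row_named(c(rep(1, 4), rep(0, 8)))
  expect_equal(predict_gene_function(low, ann)$call, "no_prediction")

  # present in nearly all ciliated species including the nonmotile class
  bio <- row_named(c(rep(1, 10), 0, 0))
  expect_equal(predict_gene_function(bio, ann)$call, "biogenesis")

  # present in motile-ciliated species, absent from every nonmotile one
  mot <- row_named(c(rep(1, 8), 0, 0, 0, 0))
  p <- predict_gene_function(mot, ann)
  expect_equal(p$call, "motility")
  expect_equal(p$conservation_fraction, 0.8)

  expect_error(predict_gene_function(low, make_annotations(sp, rep(FALSE, 12))),
               "no ciliated")
})

test_that("prediction rule matches an exhaustive truth-table evaluation", {
  sp <- sprintf("s%d", 1:6)
  ann <- make_annotations(sp, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                          motile = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  cil <- ann$is_ciliated
  nonmot <- cil & !ann$has_motile_cilia
  mot <- cil & ann$has_motile_cilia
  grid <- expand.grid(rep(list(0:1), 6))
  for (i in seq_len(nrow(grid))) {
    p <- setNames(as.integer(grid[i, ]), sp)
    cons <- mean(p[cil])
    want <- if (cons < 0.5) "no_prediction"
      else if (all(p[nonmot] == 0) && mean(p[mot]) >= 0.5) "motility"
      else "biogenesis"
    expect_equal(predict_gene_function(p, ann)$call, want)
  }
})

test_that("gaining one ciliated presence never turns biogenesis into no_prediction", {
  set.seed(77)
  sp <- sprintf("s%02d", 1:10)
  ann <- make_annotations(sp, c(rep(TRUE, 8), FALSE, FALSE),
                          motile = c(rep(TRUE, 6), FALSE, FALSE, TRUE, TRUE))
  for (rep_i in 1:50) {
    p <- setNames(as.integer(runif(10) < 0.5), sp)
    before <- predict_gene_function(p, ann)$call
    if (before != "biogenesis") next
    zero_cil <- which(p == 0 & ann$is_ciliated)
    for (j in zero_cil) {
      q <- p; q[j] <- 1L
      expect_false(predict_gene_function(q, ann)$call == "no_prediction")
    }
  }
})

test_that("universally conserved genes are exactly the planted ones", {
  sp <- c("c1", "c2", "c3", "n1", "n2", "p1")
  ann <- make_annotations(sp, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ann$major_group[6] <- "prokaryote"
  m <- rbind(
    u1 = c(1, 1, 1, 0, 0, 0),   # universal
    u2 = c(1, 1, 1, 0, 0, 1),   # presence in a prokaryote does not disqualify
    x1 = c(1, 1, 0, 0, 0, 0),   # one ciliated absence: excluded
    x2 = c(1, 1, 1, 1, 0, 0)    # present in a nonciliated eukaryote: excluded
  )
  storage.mode(m) <- "integer"
  colnames(m) <- sp
  expect_setequal(universally_conserved_genes(m, ann), c("u1", "u2"))
})
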