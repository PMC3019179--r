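test_that("templates are built from the nominal run and are well separated", {
  tpl <- make_templates(fx_nominal())
  expect_named(tpl, c("FosJun", "JunJun", "balance"))
  for (nm in names(tpl)) {
    expect_equal(tpl[[nm]]$values[1], 0)
    expect_equal(max(tpl[[nm]]$values), 1)
  }
  r <- cor(sapply(tpl, function(x) x$values))
  expect_true(all(r[upper.tri(r)] < 0.95))
  # template against itself: r = 1 -> its own label
  for (nm in names(tpl)) {
    cl <- classify_response(tpl[[nm]]$values, tpl)
    expect_equal(as.character(cl$label), nm)
    expect_equal(unname(cl$r[nm]), 1)
  }
})

test_that("classification is invariant to positive affine transforms", {
  tpl <- make_templates(fx_nominal())
  prof <- tpl$JunJun$values
  set.seed(8)
  noisy <- prof + rnorm(length(prof), 0, 0.01)
  expect_equal(as.character(classify_response(noisy, tpl)$label), "JunJun")
  expect_equal(as.character(classify_response(3.7 * noisy + 2, tpl)$label),
               "JunJun")
  # orthogonal-ish profile matches nothing
  odd <- sin(seq(0, 20 * pi, length.out = length(prof)))
  expect_equal(as.character(classify_response(odd, tpl)$label),
               "unclassified")
  # constant profile is flagged
  flat <- classify_response(rep(2, length(prof)), tpl)
  expect_equal(as.character(flat$label), "unclassified")
  expect_equal(flat$flag, "zero-variance profile")
})

test_that("unperturbed parameter sets classify as dynamic balance", {
  net <- fx_network(); p <- fx_params(); inp <- fx_inputs()
  tpl <- make_templates(fx_nominal())
  pl <- perturb_and_label(p, c("r41_k", "JNK_max"), n = 3, seed = 2,
                          network = net, inputs = inp, templates = tpl,
                          fold = 1.0001)
  expect_true(all(pl$labels == "balance"))
  expect_true(all(pl$r[, "balance"] > 0.999))
})

test_that("a planted single-threshold rule is recovered by the tree", {
  rule <- list(list(label = "JunJun", param = "x1", op = ">",
                    threshold = 1.4))
  ranges <- list(x1 = c(0.5, 2), x2 = c(0.5, 2), x3 = c(0.5, 2))
  lab <- synth_labeled_responses(rule, n = 2000, seed = 5, ranges = ranges,
                                 default = "balance")
  tree <- build_tree(lab$params, lab$labels)
  expect_equal(root_variable(tree), "x1")
  thr <- tree_nodes(tree)$threshold[1]
  expect_lt(abs(thr - 1.4) / 1.4, 0.02)
  # held-out audit
  held <- synth_labeled_responses(rule, n = 1000, seed = 99, ranges = ranges,
                                  default = "balance")
  acc <- mean(predict(tree, held$params) == held$labels)
  expect_gte(acc, 0.99)
})

test_that("a two-clause rule yields a depth-2 tree robust to label noise", {
  rule <- list(
    list(label = "JunJun", param = "x1", op = ">", threshold = 1.5),
    list(label = "FosJun", param = "x2", op = "<", threshold = 0.8))
  ranges <- list(x1 = c(0.5, 2), x2 = c(0.5, 2))
  lab <- synth_labeled_responses(rule, n = 3000, seed = 6, ranges = ranges)
  tree <- build_tree(lab$params, lab$labels)
  nd <- tree_nodes(tree)
  expect_setequal(unique(nd$var[nd$var != "<leaf>"]), c("x1", "x2"))

  noisy <- synth_labeled_responses(rule, n = 3000, seed = 7, ranges = ranges,
                                   flip = 0.05)
  tree_n <- build_tree(noisy$params, noisy$labels)
  clean <- synth_labeled_responses(rule, n = 1500, seed = 8, ranges = ranges)
  acc <- mean(predict(tree_n, clean$params) == clean$labels)
  expect_gte(acc, 0.90)
})

test_that("tree construction honors degenerate inputs and the split rule", {
  P <- data.frame(x1 = runif(50), x2 = runif(50))
  # single-class input -> depth-0 tree predicting that class
  t0 <- build_tree(P, factor(rep("balance", 50)))
  expect_true(is.na(root_variable(t0)))
  expect_true(all(predict(t0, P) == "balance"))
  # the 15%-of-smallest-class rule maps to the minimum splittable node size
  y <- factor(c(rep("a", 40), rep("b", 10)))
  tr <- build_tree(P, y, min_fraction = 0.15)
  expect_equal(tr$minsplit, max(2L, ceiling(0.15 * 10)))
  # alternative class-share reading runs and yields a valid tree
  tr2 <- build_tree(P, y, min_fraction = 0.15, rule = "class_share")
  expect_s3_class(tr2, "ap1_tree")
  # missing split variable is reported
  rule <- list(list(label = "b", param = "x1", op = ">", threshold = 0.5))
  lab <- synth_labeled_responses(rule, 500, seed = 1,
                                 ranges = list(x1 = 0:1, x2 = 0:1),
                                 default = "a")
  t1 <- build_tree(lab$params, lab$labels)
  expect_error(predict(t1, data.frame(x2 = 0.5)), "missing split variable")
  # training accuracy beats the best stump when structure is deeper
  expect_gte(mean(predict(t1, lab$params) == lab$labels), 0.95)
})

test_that("trees serialize to a node table and DOT text", {
  rule <- list(list(label = "b", param = "x1", op = ">", threshold = 0.6))
  lab <- synth_labeled_responses(rule, 500, seed = 3,
                                 ranges = list(x1 = 0:1), default = "a")
  tree <- build_tree(lab$params, lab$labels)
  nd <- tree_nodes(tree)
  expect_true(all(c("node", "var", "n", "threshold", "class") %in% names(nd)))
  dot <- tree_to_dot(tree)
  expect_match(dot, "^digraph")
  expect_match(dot, "x1")
})
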