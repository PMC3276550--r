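# Reaction-table parsing, elementary expansion, conserved moieties and
# unit conversion.

test_that("table rows expand to the correct elementary reactions", {
  net <- fullNet()
  rows <- net@rows

  # reversible receptor binding: 2 elementary reactions, printed rates
  i <- grep("^Da \\+ R <-> DaR", rows$equation)
  re <- expandEnzymeSteps(net, i)
  expect_equal(nrow(re), 2)
  expect_equal(sort(re$rate), sort(c(0.00111, 10)))
  expect_setequal(re$step, c("fwd", "back"))

  # enzyme triple: bind, unbind, catalyze with kf/kb/kcat
  i <- grep("DARPP32 \\+ PKAc <-> DARPP32_PKAc", rows$equation)
  re <- expandEnzymeSteps(net, i)
  expect_equal(nrow(re), 3)
  expect_equal(re$rate[re$step == "fwd"], 0.0027)
  expect_equal(re$rate[re$step == "back"], 8)
  expect_equal(re$rate[re$step == "cat"], 2)
  # ES complex is a registered species and the catalytic step consumes it
  es <- match("DARPP32_PKAc", net@species$name)
  cat_col <- rownames(re)[re$step == "cat"]
  expect_equal(unname(net@stoich[es, as.integer(cat_col)]), -1L)

  # kf-only row is a single irreversible reaction
  i <- grep("^GaGTP -> GaGDP", rows$equation)
  expect_equal(nrow(expandEnzymeSteps(net, i)), 1)

  # scientific-notation rates parsed exactly as printed
  i <- grep("^Da <-> Da_Ext", rows$equation)
  expect_identical(rows$kb[i], 2.00e-05)
})

test_that("elementary count equals the row-type identity", {
  net <- fullNet()
  # independent enumeration straight from the definition file
  lines <- readLines(system.file("extdata", "reactions.tsv",
                                 package = "spineRD"))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  eq <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  isEnz <- grepl("<->", eq) & grepl("<-> [^\t]*->", eq)
  isRev <- grepl("<->", eq) & !isEnz
  isIrr <- !grepl("<->", eq)
  expect_equal(nrow(net@reactions),
               2 * sum(isRev) + 1 * sum(isIrr) + 3 * sum(isEnz))
})

test_that("malformed rows are rejected with their identifier", {
  expect_error(
    toyNetwork("A + Zz -> B\t1", c("A\t0\tM:1", "B\t0\tM:1")),
    "unknown species token")
  expect_error(
    toyNetwork("A -> B\t-1", c("A\t0\tM:1", "B\t0\tM:1")),
    "negative rate")
  expect_error(
    toyNetwork("A + B + C -> D\t1",
               c("A\t0\tM:1", "B\t0\tN:1", "C\t0\tO:1", "D\t0\tM:1;N:1;O:1")),
    "second order")
  expect_error(
    toyNetwork("A -> B\t1\t2\t3", c("A\t0\tM:1", "B\t0\tM:1")),
    "complex product")
})

test_that("empty definition file yields an empty network", {
  net <- toyNetwork(character(0), c("A\t0\tM:1"))
  expect_equal(nrow(net@reactions), 0)
  expect_equal(nrow(net@rows), 0)
})

test_that("declared moieties lie in the left null space of S", {
  net <- fullNet()
  mo <- conservedMoieties(net)
  # nothing was dropped by verification
  expect_setequal(names(mo), colnames(net@composition))
  # required totals are present
  expect_true(all(c("DARPP32", "GluA1", "PP1", "Cam", "PKAc", "PKAr",
                    "CaMKII", "pmca") %in% names(mo)))
  # direct check: every reaction leaves every moiety unchanged
  for (w in mo)
    expect_true(max(abs(crossprod(w, net@stoich))) == 0)
  # CaMKII holoenzyme pair counts 2 subunits
  expect_equal(unname(mo$CaMKII[match("Complex", net@species$name)]), 2)
  # regulatory dimer of R2C carries one catalytic subunit
  expect_equal(unname(mo$PKAc[match("R2CcAMP4", net@species$name)]), 1)
})

test_that("toy reversible pair conserves its single moiety", {
  net <- toyNetwork("A <-> B\t1\t2", c("A\t0\tM:1", "B\t0\tM:1"))
  mo <- conservedMoieties(net)
  expect_equal(length(mo), 1)
  expect_equal(unname(mo$M), c(1, 1))
})

test_that("stochastic rate conversion is unit-correct", {
  # bimolecular: c = kf * 1e9 / (N_A * V_litres)
  expect_equal(stochasticRate(0.0027, 2, 0.006), 0.747, tolerance = 1e-3)
  # unimolecular rates are volume independent
  expect_identical(stochasticRate(5, 1, 0.006), 5)
  expect_identical(stochasticRate(5, 1, 10), 5)
  expect_error(stochasticRate(1, 3, 1), "order")
  expect_error(stochasticRate(1, 2, 0), "V must be")
})

test_that("dopamine exchange fixes the printed basal concentration", {
  net <- fullNet()
  i <- grep("^Da <-> Da_Ext", net@rows$equation)
  kf <- net@rows$kf[i]; kb <- net@rows$kb[i]
  expect_equal(kb * 1000000.4 / kf, 10.0, tolerance = 1e-4)
})

test_that("microscopic-reversibility loops close within 1 percent", {
  # Rates set by thermodynamic consistency must close their binding loops:
  # (1) receptor/G-protein square: Da+R, DaR+G vs G+R, GR+Da;
  # (2) holoenzyme-target squares: holoenzyme binds target then sheds R2C,
  #     vs holoenzyme sheds catalytic subunit which binds the target.
  net <- fullNet()
  rows <- net@rows
  K <- function(pattern) {
    i <- grep(pattern, rows$equation)
    expect_length(i, 1)
    rows$kf[i] / rows$kb[i]
  }
  # receptor loop
  lhs <- K("^Da \\+ R <-> DaR$") * K("^DaR \\+ Gabg <-> ")
  rhs <- K("^Gabg \\+ R <-> ") * K("^GabgR \\+ Da <-> ")
  expect_equal(lhs, rhs, tolerance = 0.01)
  # holoenzyme-target loops: bind, dissociate vs activate, bind
  Kact <- K("^PKAcAMP4 <-> R2CcAMP4 \\+ PKAc$")
  loops <- list(
    c("^PKAcAMP4 \\+ PDE10 <-> PKAcAMP4PDE10$",
      "^PKAcAMP4PDE10 <-> PKAcPDE10 \\+ R2CcAMP4$",
      "^PKAc \\+ PDE10 <-> PKAcPDE10 "),
    c("^PKAcAMP4 \\+ PDE10cAMP <-> ",
      "^PKAcAMP4PDE10cAMP <-> ",
      "^PKAc \\+ PDE10cAMP <-> "),
    c("^PP2A_B56d \\+ PKAcAMP4 <-> ",
      "^PKAcAMP4PP2A_B56d <-> ",
      "^PP2A_B56d \\+ PKAc <-> "),
    c("^PKAcAMP4 \\+ GluA1 <-> ",
      "^GluA1_PKAcAMP4 <-> ",
      "^GluA1 \\+ PKAc <-> "),
    c("^p34DARPP32 \\+ PKAcAMP4 <-> ",
      "^p34DARPP32_PKAcAMP4 <-> ",
      "^DARPP32 \\+ PKAc <-> "))
  for (lp in loops) {
    expect_equal(K(lp[1]) * K(lp[2]), Kact * K(lp[3]), tolerance = 0.01)
  }
})

test_that("definition file round-trips bit-exactly", {
  net <- fullNet()
  src <- system.file("extdata", "reactions.tsv", package = "spineRD")
  out <- withr::local_tempfile(fileext = ".tsv")
  writeReactionTable(net, out, sourceFile = src)
  expect_identical(readLines(out), readLines(src))
})

test_that("configuration variants edit the network as specified", {
  net <- fullNet()
  cfg <- spatialConfig(dopamineD = 50, d32DiffusionMode = "frozen",
                       pT75PKABlock = TRUE)
  mod <- applyConfig(net, cfg)
  sp <- mod@species
  expect_equal(sp$D[sp$name == "Da"], 50)
  expect_true(all(sp$D[grepl("DARPP32", sp$name)] == 0))
  # p75/PKAc binding removed, other PKAc reactions intact
  i75 <- match("p75DARPP32", sp$name); ic <- match("PKAc", sp$name)
  re <- mod@reactions
  expect_false(any(re$r1 %in% c(i75) & re$r2 %in% c(ic) |
                     re$r1 %in% c(ic) & re$r2 %in% c(i75)))
  expect_lt(nrow(re), nrow(net@reactions))
  # PKA-bound-only freeze keeps free DARPP-32 mobile
  mod2 <- applyConfig(net, spatialConfig(
    dopamineD = 50, d32DiffusionMode = "pka.bound.frozen"))
  sp2 <- mod2@species
  expect_equal(sp2$D[sp2$name == "DARPP32"], 10.6)
  expect_equal(sp2$D[sp2$name == "DARPP32_PKAc"], 0)
})
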