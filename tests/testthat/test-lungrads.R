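test_that("the shipped default table loads, validates, and is versioned", {
  tab <- loadRuleTable()
  expect_s4_class(tab, "RuleTable")
  expect_identical(tab@version, "1.1-default")
})

test_that("assignments follow the v1.1 cut-offs in the branch structure", {
  tab <- loadRuleTable()
  expect_identical(assignCategory("Solid", "Lobulated", 5.0, tab), "2")
  expect_identical(assignCategory("Solid", "Spiculated", 6.0, tab), "3")
  expect_identical(assignCategory("Solid", "Indistinct", 8.0, tab), "4A")
  expect_identical(assignCategory("Solid", "SharpCircumscribed", 15.0, tab), "4B")
  expect_identical(assignCategory("PureGGO", "SharpCircumscribed", 31.0, tab), "3")
  expect_identical(assignCategory("PureGGO", "Spiculated", 29.9, tab), "2")
  expect_identical(assignCategory("Subsolid", "Lobulated", 5.9, tab), "2")
  expect_identical(assignCategory("Subsolid", "SharpCircumscribed", 6.0, tab), "3")
  expect_identical(assignCategory("Subsolid", "Spiculated", 9.0, tab), "4B")
  expect_identical(assignCategory("Subsolid", "Indistinct", 7.9, tab), "4A")
  expect_error(assignCategory("Solid", "Lobulated", 0, tab), "positive")
})

test_that("coverage gaps and conflicting overlaps are load-time errors", {
  solid_only <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: t", "rules:",
               "  - {texture: [Solid], margin: '*', size: [0, .inf], category: '2'}"),
             solid_only)
  expect_error(loadRuleTable(solid_only), "Subsolid|PureGGO")
  conflict <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: t", "rules:",
               "  - {texture: [Solid, Subsolid, PureGGO], margin: '*', size: [0, .inf], category: '2'}",
               "  - {texture: [Solid], margin: '*', size: [6, 8], category: '3'}"),
             conflict)
  expect_error(loadRuleTable(conflict), "determinism")
  gap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: t", "rules:",
               "  - {texture: [Solid, Subsolid, PureGGO], margin: '*', size: [0, 10], category: '2'}",
               "  - {texture: [Solid, Subsolid, PureGGO], margin: '*', size: [12, .inf], category: '2'}"),
             gap)
  expect_error(loadRuleTable(gap), "totality")
})

test_that("truth-table enumeration agrees with assignCategory everywhere", {
  tab <- loadRuleTable()
  grid <- c(1, 5.9, 6, 7, 8, 14.9, 15, 29, 30, 40)
  tt <- enumerateTruthTable(tab, grid)
  expect_identical(nrow(tt), 3L * 4L * length(grid))
  expect_true(all(tt$category %in% lungRADSLevels()))
  for (i in seq_len(nrow(tt)))
    expect_identical(tt$category[i],
                     assignCategory(tt$texture[i], tt$margin[i],
                                    tt$size_mm[i], tab))
  expect_error(enumerateTruthTable(tab, numeric(0)), "empty")
})

test_that("margin only matters for Subsolid; category is monotone in size", {
  tt <- enumerateTruthTable(loadRuleTable(),
                            c(0.5, 3, 6, 7.5, 8, 12, 15, 20, 30, 45))
  for (tex in c("Solid", "PureGGO")) {
    sub <- tt[tt$texture == tex, ]
    per_size <- tapply(sub$category, sub$size_mm,
                       function(x) length(unique(x)))
    expect_true(all(per_size == 1L))
  }
  ord <- c("2" = 1L, "3" = 2L, "4A" = 3L, "4B" = 4L)
  for (tex in textureLevels()) for (mar in marginLevels()) {
    sub <- tt[tt$texture == tex & tt$margin == mar, ]
    sub <- sub[order(sub$size_mm), ]
    expect_true(all(diff(ord[sub$category]) >= 0L))
  }
})

test_that("randomized queries always match exactly one first rule", {
  tab <- loadRuleTable()
  set.seed(7)
  for (i in 1:200) {
    tex <- sample(textureLevels(), 1)
    mar <- sample(marginLevels(), 1)
    size <- runif(1, 0.01, 60)
    cat <- assignCategory(tex, mar, size, tab)
    expect_true(cat %in% lungRADSLevels())
    hits <- Filter(function(r) lungReporter:::.ruleMatches(r, tex, mar, size),
                   tab@rules)
    expect_true(all(vapply(hits, `[[`, "", "category") == cat))
  }
})
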