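# Domain types, file formats and unit conversions.

test_that("boundary file lines map to objects and malformed lines error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "s1\t7\t10.0\t12.0\t0,0 4,0 4,4 0,4"), path)
  objs <- read_boundary_file(path)
  expect_length(objs, 1)
  expect_equal(objs[[1]]$object_id, 7L)
  expect_equal(objs[[1]]$centroid, c(10, 12))
  expect_equal(nrow(objs[[1]]$boundary), 4)

  writeLines("s1\t7\t1\t1\t0,0 1,1", path)
  expect_error(read_boundary_file(path), "polygon has 2 vertices")
  writeLines("s1\t7\t1\t1", path)
  expect_error(read_boundary_file(path), "expected 5 tab-separated fields")
})

test_that("missing centroid falls back to the vertex mean", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t3\tNA\tNA\t0,0 2,0 2,2 0,2", path)
  obj <- read_boundary_file(path)[[1]]
  expect_equal(obj$centroid, c(1, 1))
})

test_that("boundary write/read round-trip is the identity on random slides", {
  set.seed(42)
  objs <- lapply(seq_len(100), function(i) {
    structure(list(slide_id = "s9", object_id = i,
                   centroid = c(runif(1, 0, 900), runif(1, 0, 900)),
                   boundary = random_polygon(sample(3:9, 1),
                                             runif(1, 20, 880),
                                             runif(1, 20, 880))),
              class = "hist_object")
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_boundary_file(objs, path)
  back <- read_boundary_file(path)
  expect_length(back, 100)
  for (i in c(1, 37, 100)) {
    expect_equal(back[[i]]$object_id, objs[[i]]$object_id)
    expect_equal(back[[i]]$centroid, objs[[i]]$centroid, tolerance = 1e-5)
    expect_equal(back[[i]]$boundary, objs[[i]]$boundary, tolerance = 1e-5)
  }
})

test_that("boundary writer rejects mixed slides and handles empty lists", {
  objs <- list(
    structure(list(slide_id = "a", object_id = 1L, centroid = c(1, 1),
                   boundary = random_polygon()), class = "hist_object"),
    structure(list(slide_id = "b", object_id = 2L, centroid = c(1, 1),
                   boundary = random_polygon()), class = "hist_object"))
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_boundary_file(objs, path), "share a slide_id")
  write_boundary_file(list(), path)
  expect_length(read_boundary_file(path), 0)
})

test_that("feature store validation raises distinct, named errors", {
  set.seed(1)
  feats <- matrix(rnorm(20), 5, 4)
  cent <- cbind(1:5, 1:5)
  expect_s3_class(feature_store(feats, 1:5, rep("s", 5), cent),
                  "feature_store")
  expect_error(feature_store(feats, 1:4, rep("s", 5), cent),
               "object_ids")
  expect_error(feature_store(feats, 1:5, rep("s", 4), cent),
               "slide_ids")
  expect_error(feature_store(feats, 1:5, rep("s", 5), cent[1:4, ]),
               "centroids")
  feats_bad <- feats; feats_bad[2, 2] <- NaN
  expect_error(feature_store(feats_bad, 1:5, rep("s", 5), cent),
               "[Nn]on-finite")
  expect_error(feature_store(feats, c(1, 1, 2, 3, 4), rep("s", 5), cent),
               "unique")
})

test_that("feature store save/load round-trip preserves rows and order", {
  set.seed(7)
  n <- 120
  store <- feature_store(matrix(rnorm(n * 48), n, 48),
                         sample.int(10 * n, n),
                         sample(c("sA", "sB"), n, TRUE),
                         cbind(runif(n, 0, 2000), runif(n, 0, 1500)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "store")
  save_feature_store(store, path)
  back <- load_feature_store(path)
  expect_equal(back$object_ids, store$object_ids)
  expect_equal(back$slide_ids, store$slide_ids)
  expect_equal(back$feature_names, store$feature_names)
  expect_equal(back$features, store$features, tolerance = 1e-6)
  expect_equal(back$centroids, store$centroids, tolerance = 1e-6)

  file.remove(file.path(path, "feature_names.txt"))
  expect_error(load_feature_store(path), "missing member feature_names.txt")
})

test_that("centroid conversion scales per slide and rejects unknown slides", {
  store <- feature_store(matrix(0, 3, 2), 1:3, c("a", "a", "b"),
                         rbind(c(100, 200), c(10, 10), c(100, 200)))
  slides <- slide_meta(c("a", "b"), c(1000, 1000), c(1000, 1000),
                       mpp = c(0.25, 1))
  um <- centroids_to_microns(store, slides)
  expect_equal(um[1, ], c(25, 50))
  expect_equal(um[2, ], c(2.5, 2.5))
  expect_equal(um[3, ], c(100, 200))  # mpp = 1 is the identity
  # linearity: scaling mpp scales outputs
  slides2 <- slides; slides2$mpp <- slides$mpp * 3
  expect_equal(centroids_to_microns(store, slides2), um * 3)
  expect_error(centroids_to_microns(store, slides[1, ]),
               "missing slide_id")
})

test_that("label files round-trip with ignore entries and provenance", {
  ls <- label_set(c(5L, 9L, 11L), c(1L, -1L, NA),
                  source = c("seed", "instance", "review"),
                  iteration = c(0L, 2L, 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_label_file(ls, path)
  back <- read_label_file(path)
  expect_equal(back$object_id, ls$object_id)
  expect_equal(back$label, ls$label)
  expect_equal(back$source, ls$source)
  expect_equal(back$iteration, ls$iteration)
})

test_that("label sets enforce the class encoding and the ignore semantics", {
  expect_error(label_set(1:2, c(2L, 1L)), "\\+1, -1 or NA")
  expect_error(label_set(c(1, 1), c(1L, -1L)), "duplicate")
  ls <- label_set(1:4, c(1L, -1L, NA, 1L))
  act <- active_labels(ls)
  expect_equal(act$object_id, c(1L, 2L, 4L))
})
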