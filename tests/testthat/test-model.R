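# Architecture assembly: determinism, shape contracts at strides 8/16/32,
# and the qualitative parameter-budget structure of the variant family.

test_that("building the same config twice gives identical networks", {
  cfg <- model_config("yolov8n", nc = 1, imgsz = 64, width_mult = 0.25)
  m1 <- build_model(cfg, seed = 42)
  m2 <- build_model(cfg, seed = 42)
  expect_identical(m1$params, m2$params)
  expect_identical(count_parameters(m1), count_parameters(m2))
  expect_error(build_model(list()), "model_config")
  expect_error(model_config("resnet"), "arg")
})

test_that("all variants emit three prediction maps at strides 8/16/32", {
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (v in c("yolov8n", "mlg-yolo")) {
    m <- build_model(model_config(v, nc = 1, imgsz = 64, width_mult = 0.25))
    outs <- forward_model(m, x)
    expect_length(outs, 3L)
    expect_equal(lapply(outs, function(o) dim(o)[1:2]),
                 list(c(8L, 8L), c(4L, 4L), c(2L, 2L)))
    # 4 * reg_max box channels + nc class channels
    expect_true(all(vapply(outs, function(o) dim(o)[3], numeric(1)) == 65))
  }
})

test_that("parameter counts are deterministic closed forms of the config", {
  n1 <- count_parameters(build_model(model_config("mlg-yolo"), seed = 1))
  n2 <- count_parameters(build_model(model_config("mlg-yolo"), seed = 99))
  expect_identical(n1, n2)   # independent of weight values
})

test_that("parameter budget ordering matches the lightweighting structure", {
  np <- vapply(c(yolov8n = "yolov8n", lsk = "yolov8n-lsk",
                 gs = "yolov8n-gsconv", mv = "mobilevit",
                 mvlsk = "mobilevit-lsk", mvgs = "mobilevit-gsconv",
                 full = "mlg-yolo"),
               function(v) count_parameters(build_model(model_config(v))),
               numeric(1))
  # MobileViT-backbone variants ~1.17-1.19 M, far below ~2.9-3.2 M
  expect_true(all(np[c("mv", "mvlsk", "mvgs", "full")] > 1.1e6 &
                    np[c("mv", "mvlsk", "mvgs", "full")] < 1.2e6))
  expect_true(all(np[c("yolov8n", "lsk", "gs")] > 2.9e6 &
                    np[c("yolov8n", "lsk", "gs")] < 3.2e6))
  # LSK strictly adds a small delta; GSConv strictly reduces the neck
  expect_gt(np["lsk"], np["yolov8n"])
  expect_lt(np["lsk"] - np["yolov8n"], 20000)
  expect_lt(np["gs"], np["yolov8n"])
  expect_gt(np["mvlsk"], np["mv"])
  expect_lt(np["mvgs"], np["mv"])
})

test_that("FLOPs scale quadratically with input size for the conv baseline", {
  m <- build_model(model_config("yolov8n", nc = 1))
  expect_equal(count_flops(m, 640), 4 * count_flops(m, 320),
               tolerance = 1e-12)
})

test_that("model summary reports reproducible counts and both storage sizes", {
  cfg <- model_config("mlg-yolo", nc = 1)
  r1 <- summarize_model(cfg)
  r2 <- summarize_model(cfg)
  expect_identical(r1$parameters, r2$parameters)
  expect_equal(r1$size_mb_fp16, r1$size_mb_fp32 / 2)
  expect_equal(r1$size_mb_fp32, r1$parameters * 4 / 2^20)
})

test_that("lsk insertion point is configurable across neck scales", {
  base <- count_parameters(build_model(model_config("yolov8n")))
  for (at in c("P3", "P4", "P5")) {
    m <- build_model(model_config("yolov8n-lsk", lsk_at = at))
    expect_gt(count_parameters(m), base)
  }
  # deeper insertion points touch wider channels, so cost more parameters
  p3 <- count_parameters(build_model(model_config("yolov8n-lsk", lsk_at = "P3")))
  p4 <- count_parameters(build_model(model_config("yolov8n-lsk", lsk_at = "P4")))
  p5 <- count_parameters(build_model(model_config("yolov8n-lsk", lsk_at = "P5")))
  expect_true(p3 < p4 && p4 < p5)
})
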