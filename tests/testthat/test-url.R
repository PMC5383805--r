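test_that("registrable domains are extracted with subdomains stripped", {
  expect_identical(extract_domain("http://en.wikipedia.org/wiki/Second_Amendment"),
                   "wikipedia.org")
  expect_identical(extract_domain("https://shop.example.com/ammo?id=1"),
                   "example.com")
  expect_identical(extract_domain("http://portal.ct.state.us/page"),
                   "ct.state.us")
  expect_identical(extract_domain("https://a.b.news.example.co.uk/x"),
                   "example.co.uk")
  expect_identical(extract_domain("HTTPS://WWW.GunDepot.COM/sale"),
                   "gundepot.com")
  expect_identical(extract_domain("https://user:pw@sub.example.org:8080/p#f"),
                   "example.org")
})

test_that("unparseable URLs yield NA instead of an error", {
  expect_identical(extract_domain(c("", "no spaces here!", "http://",
                                    "http://192.168.0.1/x", "http://com/")),
                   rep(NA_character_, 5))
})

test_that("TLD categorisation follows the ordered suffix rules", {
  expect_identical(
    tld_category(c("gundepot.com", "wikipedia.org", "ct.state.us", "atf.gov",
                   "navy.mil", "firearmlaw.edu", "example.co.uk", "show.tv",
                   "something.us")),
    c("commercial", "noncommercial", "government", "government", "government",
      "educational_institution", "other", "other", "other"))
})

test_that("content and advocacy lookups fall back for unknown domains", {
  reg <- domain_registry(data.frame(
    domain = c("gunshop.example", "news.example", "nra-like.org"),
    content_category = c("retail", "news", "educational"),
    advocacy = c(NA, NA, "gun_rights")))
  expect_identical(content_category("gunshop.example", reg), "retail")
  expect_identical(content_category("mystery.net", reg), "other")
  expect_identical(advocacy_view("nra-like.org", reg), "gun_rights")
  expect_identical(advocacy_view("wikipedia.org", reg), NA_character_)
  expect_identical(advocacy_view(
    c("stopgunviolence.org", "rifleassociation.org"), default_registry()),
    c("gun_control", "gun_rights"))
})

test_that("duplicate registry domains are rejected at load time", {
  expect_error(domain_registry(data.frame(
    domain = c("a.com", "a.com"), content_category = c("retail", "news"))),
    "more than once")
  expect_error(domain_registry(data.frame(
    domain = "a.com", content_category = "shopping")), "content")
  expect_error(read_registry("does/not/exist.csv"), "not found")
})

test_that("class labels join content and TLD deterministically", {
  expect_identical(class_label("retail", "commercial"), "retail content, .com")
  expect_identical(class_label("educational", "noncommercial"),
                   "educational content, .org")
  expect_identical(class_label("other", "other"), "other content, .other")
  expect_identical(class_label("educational", "educational_institution"),
                   "educational content, .edu")
})

test_that("log classification is pure and partitions every record", {
  log <- generate_log(tiny_config(seed = 31))
  a <- classify_log(log)
  b <- classify_log(log)
  expect_identical(a, b)
  ok <- !a$url_error
  expect_true(all(!is.na(a$tld_category[ok])))
  expect_true(all(!is.na(a$content_category[ok])))
  # partition: class counts sum back to the record count
  expect_identical(sum(table(a$class_label[ok])), sum(ok))
})
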