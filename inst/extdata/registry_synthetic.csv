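domain,content_category,advocacy
gundepot.com,retail,
ammoexchange.com,retail,
sportsmansfinder.com,retail,
bikebarn.com,retail,
eveningnews.com,news,
gazette.com,news,
cyclingweekly.co.uk,news,
wikipedia.org,educational,
gunsafetycourse.com,educational,
firearmlaw.edu,educational,
constitutioncenter.org,educational,
firearms-bureau.gov,educational,
ct.state.us,other,
screenbuzz.com,showbiz,
rifleassociation.org,educational,gun_rights
gunowners-alliance.org,educational,gun_rights
stopgunviolence.org,educational,gun_control
ceasefirecoalition.org,educational,gun_control
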