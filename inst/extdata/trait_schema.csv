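"trait","category"
"feeding habits","collector-filterer"
"feeding habits","collector-gatherer"
"feeding habits","piercer"
"feeding habits","predator"
"feeding habits","scraper"
"feeding habits","shredder"
"feeding habits","parasite"
"respiration","tegument"
"respiration","gill"
"respiration","plastron"
"respiration","spiracle"
"body form","streamlined"
"body form","flattened"
"body form","cylindrical"
"body form","spherical"
"maximum body size (mm)","<2.5"
"maximum body size (mm)","2.5-5"
"maximum body size (mm)","5-10"
"maximum body size (mm)","10-20"
"maximum body size (mm)","20-40"
"maximum body size (mm)","40-80"
"body flexibility (deg)","none (<10)"
"body flexibility (deg)","low (10-45)"
"body flexibility (deg)","high (>45)"
"locomotion","flier"
"locomotion","surface swimmer"
"locomotion","full water swimmer"
"locomotion","crawler"
"locomotion","burrower"
"locomotion","temporarily attached"
"reproduction","asexual"
"reproduction","clutches cemented"
"reproduction","clutches free"
"reproduction","clutches in vegetation"
"reproduction","clutches terrestrial"
"reproduction","isolated eggs clutches"
"reproduction","isolated eggs free"
"reproduction","ovoviviparity"
"exoskeleton hardness","none"
"exoskeleton hardness","high"
"exoskeleton hardness","moderate"
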