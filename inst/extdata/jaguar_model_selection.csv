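model,aicc,delta,weight_reported,modellik_reported
"phi(.) gamma(random,.) p(sex*era(./time))",3351.69,0.00,0.70,1.00
"phi(sex) gamma(random,.) p(sex*era(./time))",3353.77,2.08,0.25,0.35
"phi(time) gamma(random,.) p(sex*era(./time))",3358.19,6.50,0.03,0.04
"phi(sex(time/.)) gamma(random,.) p(sex*era(./time))",3359.04,7.35,0.02,0.03
"phi(sex(./time)) gamma(random,.) p(sex*era(./time))",3364.13,12.44,0.00,0.00
"phi(sex*time) gamma(random,.) p(sex*era(./time))",3369.86,18.17,0.00,0.00
"phi(sex*time) gamma(random,.) p(sex*era)",3381.88,30.19,0.00,0.00
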