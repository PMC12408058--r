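surface	doctime	expected
yesterday	2022-04-29	2022-04-28
yesterday	2013-05-02	2013-05-01
today	2013-05-02	2013-05-02
later today	2013-05-02	2013-05-02
tomorrow	2013-05-02	2013-05-03
last week	2013-05-02	2013-04-25
10/18/2033	2020-01-01	2033-10-18
2013-06-20	2020-01-01	2013-06-20
August 1, 2012	2020-01-01	2012-08-01
August 1 2012	2020-01-01	2012-08-01
July 2055	2013-05-02	2055-07
December 2055	2013-05-02	2055-12
January 2013	2013-05-02	2013-01
2055	2013-05-02	2055
1999	2013-05-02	1999
3 weeks ago	2041-03-20	2041-02-27
10 days ago	2020-03-05	2020-02-24
0 days ago	2020-05-05	2020-05-05
4 weeks ago	2020-05-05	2020-04-07
1 week ago	2020-05-05	2020-04-28
2 months ago	2020-03-31	2020-01-31
1 month ago	2020-03-31	2020-02-29
last Thursday	2013-05-02	2013-04-25
last Wednesday	2013-05-02	2013-05-01
last Friday	2013-05-02	2013-04-26
last Monday	2013-05-02	2013-04-29
last Sunday	2013-05-02	2013-04-28
6/4/2027	2020-01-01	2027-06-04
12/31/1999	2020-01-01	1999-12-31
11/2/2046	2020-01-01	2046-11-02
February 29, 2020	2020-01-01	2020-02-29
February 29, 2019	2020-01-01	UNKNOWN
13/10/2033	2020-01-01	UNKNOWN
July	2055-12-01	2055-07
some unseen idiom	2020-01-01	UNKNOWN
next week	2020-01-01	UNKNOWN
spring 2020	2020-06-01	UNKNOWN
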